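Package: famagg
Title: Familial Aggregation and Family-Based Heritability of Dietary Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pedigree-based tools for studying familial resemblance of
    quantitative phenotypes such as food-group intakes. Parses PLINK-style
    pedigree files, classifies relative pairs (parent-offspring, siblings,
    spouses, second-degree classes), computes kinship and additive relationship
    matrices by the recursive tabular method, prepares phenotypes
    (energy-intake filtering, servings per 1000 kcal adjustment, food-group
    aggregation, age adjustment, rank-based inverse-normal or Box-Cox
    normalization), estimates interclass and double-entry intraclass familial
    correlations with family-jackknife standard errors, and fits
    kinship-covariance random-effects models for heritability by Gibbs MCMC
    (Gaussian and probit-liability links) and by profiled maximum likelihood,
    with split Gelman-Rubin convergence diagnostics. Includes a synthetic
    family-data generator with known additive-genetic, couple-environment and
    assortative-mating structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
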