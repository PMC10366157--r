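---
title: "Familial aggregation and family-based heritability: models and methods"
author: "famagg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial aggregation and family-based heritability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famagg)
```

# The scientific problem

Food choices run in families: spouses eat from the same pot, parents shape
their children's habits, and relatives share genes that influence taste and
appetite. Two classical quantities summarize this. *Familial correlations*
(ICCs) measure how similar trait values are within a class of relative pairs
— mother–daughter, sibling, spouse, and so on. *Family-based heritability*
(h²) is the share of phenotypic variance attributable to a pedigree-structured
genetic component under a kinship-covariance random-effects model. famagg
implements both, together with everything needed around them: pedigree
parsing and validation, relative-pair classification, kinship matrices,
phenotype preparation, and a synthetic family generator so every stage can be
validated against known truth.

# Pedigrees, pairs and kinship

A pedigree is read from PLINK-style columns (family, individual, father,
mother, sex). Validation enforces a DAG, male fathers/female mothers and
globally unique ids; parents referenced but not listed are added as founders,
and an individual missing one parent is treated as a half-founder.

Relative pairs are classified by explicit ancestor-link rules rather than by
kinship thresholds, so inbreeding cannot mislabel a class. Spouses are not a
recorded field in the pedigree format; we define a spouse pair as two
individuals listed as father and mother of at least one common child, which
is derivable from any pedigree file. Classification precedence is
parent–offspring, full sibling, half sibling, spouse, grandparent, avuncular,
first cousin; every pair receives at most one label and unclassifiable pairs
are omitted. Cousins are reported with the second-degree group, following the
usual layout of relative-pair information tables in family studies.

Kinship uses the recursive tabular method in generation order (ties broken by
id for reproducibility): founders have φ·self = 1/2 and zero kinship with
everyone before them; a non-founder gets the average of its parents' rows and
φ·self = (1 + φ(father, mother))/2. The additive relationship matrix is
A = 2φ. Individuals from different families are unrelated, so A is block
diagonal; `relationshipBlocks()` keeps it that way, which is what makes
cohort-scale model fits cheap (all eigendecompositions run block by block).
Before any factorization a ridge of 1e-8 is added to the diagonal of A,
purely for numerical Cholesky/eigen robustness on semi-definite pedigrees.

# Phenotype preparation

Raw inputs are servings/day per food variable plus age, sex and total energy
intake (kcal/day). Preparation proceeds in fixed, auditable states:

1. **Energy plausibility filter** (`filterEnergy`): rows with energy strictly
   below 800 or strictly above 4200 kcal/day are excluded (boundary values
   retained); missing or non-positive energies are excluded as
   `invalid_energy`. Every exclusion is logged with a reason.
2. **Energy adjustment** (`energyAdjust`): servings/day become servings per
   1000 kcal, x / (energy/1000).
3. **Food-group aggregation** (`aggregateGroups`): groups are row sums of
   member items and may overlap (total meat contains red meat).
4. **Age adjustment and normalization** (`prepareTraits`): each trait is
   regressed on age (simple linear fit, pooled across sexes by default since
   sex enters the heritability model as a fixed effect; a per-sex option
   exists) and the residuals are normalized. The default normalizer is the
   rank-based inverse-normal transform with Blom offset
   (r − 3/8)/(n + 1/4), average ranks on ties, rescaled to exactly unit
   variance. The alternative is Box–Cox: residuals are shifted to be
   strictly positive (minimum mapped to a small positive offset of
   0.001·SD), λ is chosen by profile maximum likelihood on [−2, 2], and the
   transformed values are z-scored. The inverse-normal default is standard
   practice for family-based analysis of skewed intake data; Box–Cox is
   provided as the named classical alternative. (A further transformation
   sometimes used with classical pedigree likelihoods, the George–Elston
   transform, is not implemented: no closed formula was available to
   implement it faithfully.)

Cohort-style exclusions (pregnancy, disease history, …) are generic boolean
column filters (`filterCriterion`), since they are inclusion criteria rather
than statistics.

# Familial correlations

For a pair class and trait, the estimator depends on whether the two roles
are distinguishable:

* **Interclass** (product-moment over ordered pairs) for parent–offspring
  dyads, spouses, brother–sister, grandparent and avuncular pairs; the
  "senior" role is always stored first.
* **Intraclass by double entry** for exchangeable classes (sister–sister,
  brother–brother, half-sibling, cousin): each pair contributes both
  orderings and a common mean and variance are used.

Pairs are equally weighted and individuals appearing in many pairs stay in
all of them. Because pairs within a family are dependent, the standard error
is a leave-one-*family*-out jackknife (computed exactly via per-family
sufficient statistics), and the p-value is two-sided normal on ICC/SE. The
exact estimator variant and standard-error formula used by classical
pedigree software (e.g. the FCOR routine) are not fully documented; the
jackknife is our documented substitute and is flagged as such in the report
metadata (`attr(report, "se_method")`). No multiplicity adjustment is
applied (α = 0.05 per test); the report flags non-significant rows rather
than dropping them, with an option to reproduce the report-significant-only
convention.

# The heritability model

For a prepared trait y the model is

  y = Xβ + g + e,  g ~ N(0, A σ²g),  e ~ N(0, I σ²e),

with X containing intercept, age and sex, and h² = σ²g/(σ²g + σ²e). Some
formulations write the genetic covariance as K σ²g with K the kinship
matrix; we use A = 2K by default so that σ²g is the additive genetic
variance and h² keeps its standard meaning — note the choice rescales not
only σ²g but h² itself, so it matters and is stated prominently here. A
linear predictor with no residual term cannot define a likelihood, so the
Gaussian model includes e explicitly; the probit model fixes σ²e ≡ 1 on the
liability scale.

No household/common-environment variance component is fitted — deliberately,
to mirror the model under study — so estimated h² absorbs shared family
environment. The synthetic generator *does* include a couple-environment
component, which is exactly what lets the tests demonstrate this absorption
property rather than hide it.

## Gibbs sampler

The model is rotated once into the eigenbasis of A = UDUᵀ (blockwise by
family), where the genetic effects have independent full conditionals:

* β | rest: multivariate normal around the GLS solution;
* transformed genetic effects a | rest: independent normals with precision
  1/σ²e + 1/(σ²g d·i); eigenvalues below 1e-10 pin a·i to 0;
* σ²g, σ²e | rest: scaled inverse chi-square.

Priors on both variances are scaled inverse chi-square with 5 degrees of
freedom and scale set so the prior mode splits the observed phenotypic
variance 50:50 (the common default behaviour of Bayesian whole-genome
regression software); both are overridable. The long-run preset is 400000
iterations, 200000 burn-in, thin 40 — retaining exactly
floor((400000−200000)/40) = 5000 draws; tests and examples run scaled-down
chains (typically 6000–20000 iterations), which the retained-draw arithmetic
covers identically. Chain c uses seed + 99991(c−1), and a (seed, settings)
pair reproduces draws bit for bit.

For binary traits the probit-liability sampler augments each sweep with
truncated-normal liabilities around η = Xβ + g (inverse-CDF sampling,
clamped at 1e-12 for numerical safety) and reports h² on the liability
scale, σ²g/(σ²g + 1).

Convergence is monitored by the split Gelman–Rubin statistic (each chain
halved; potential scale reduction factor) on h² and both variances, with the
conventional 1.03 threshold raising a warning flag on the fit rather than an
exception. Constant chains return R̂ = 1 by convention, since the ratio is
undefined at zero variance.

## Classical likelihood arm

With ρ = σ²g/(σ²g+σ²e), V = σ²p(ρA + (1−ρ)I) diagonalizes in the same
eigenbasis, so the likelihood is profiled over ρ with β and σ²p in closed
form at each value — a single 1-D optimization, checked in tests against a
dense 200-point grid oracle. The LRT of σ²g = 0 uses the 50:50 boundary
mixture ½χ²₀ + ½χ²₁. Two flags matter: `boundary` (estimate pinned at 0 or
1) and `flat_likelihood` (ρ unidentifiable, e.g. A proportional to the
identity when everyone is unrelated, in which case h² is reported as NA).

## Posterior-mean behaviour near the boundary

h² is bounded below by 0, so under a true null the posterior is right-skewed
and its *mean* sits well above the MLE at modest sample sizes: exact 2-D
numerical integration of the marginal posterior (which the test suite
compares against the sampler) gives a posterior mean around 0.15–0.23 at
n ≈ 800 under this package's default family structure, for any reasonable
variance prior. This is a property of the correct posterior, not an
implementation artifact. Null-recovery checks are therefore run at the full
cohort scale of 4338 families (≈ 15000 individuals), where the posterior
mean concentrates below 0.10; the block-diagonal machinery makes such runs
take seconds. The same effect is stronger for the probit arm (binary data
carry roughly half the information), whose null and recovery checks run at
multi-thousand-family scale. Readers should apply the same caution to real
analyses: a posterior-mean h² of 10–15% at a few hundred families is
compatible with zero heritability, which is why the likelihood-ratio test
and the credible interval are reported alongside the mean.

# The synthetic generator

`simulationConfig()` fixes the study conditions: a mix of singleton
"families" (36%) and 2–3-generation pedigrees with sibships of 1–6 children
(mean ≈ 1.66, matching a cohort sibship mean of 1.6), third-generation
couples formed with probability 0.25, families capped at 32 members — giving
a mean family size within 10% of 3.20. The latent trait is

  ℓ = β·age(age − mean) + β·sex·[male] + g + c + e,

with g drawn from N(0, A h²) by family-block Cholesky, c a couple-shared
environmental effect of variance c² (shared by the two members of each
couple, inherited by nobody — the device that makes spouse ICCs exceed
parent–offspring ICCs), and couple residuals drawn bivariate-normal with
correlation `spousalR` (phenotypic assortment at couple formation; for
jointly normal residuals this is equivalent to rank coupling). Defaults
h² = 0.25, c² = 0.15, spousalR = 0.2 reproduce the qualitative spouse >
parent–offspring > 0 ordering with spouse correlations near 0.27.

Observed data are made FFQ-like: reported energy is normal (2300 ± 500
kcal/day) clipped into the plausible window, with a misreport fraction
(default 668/10468 ≈ 6.4%) pushed strictly outside 800–4200 kcal/day so the
filter is exercised with a realistic exclusion count; servings/day are the
exponential back-transform exp(μ·s + σ·s ℓ)·energy/1000, positive and
right-skewed, so inverse-normal preparation is exercised non-trivially.

What the generator does *not* emulate: item-level FFQ structure, measurement
error and reporting bias correlated with covariates, secular/survey-wave
effects, household clustering beyond couples, and assortative mating with a
genetic mechanism. Passing recovery tests therefore show the estimators are
correct under the stated model, not that real cohort estimates are unbiased
— in particular, h² from this model absorbs shared-household variance in
real data exactly as it absorbs c² in simulation when c² > 0.

# Numerical choices and limitations

* Diagonal ridge 1e-8 on A before factorization; eigenvalues below 1e-10
  treated as null directions.
* Generation order with lexicographic tie-breaks makes kinship, pair lists
  and draws deterministic for a given input file and seed.
* Estimates from fewer than 3 complete pairs, single-family classes or
  zero-variance roles are suppressed with machine-readable reasons rather
  than returned as numbers.
* Box–Cox requires strictly positive values; the shift policy above is a
  pragmatic choice and λ is only interpretable relative to the shifted
  scale.
* Problem sizes in the tests (hundreds of families for recovery and
  coverage, thousands for null checks, 1e5 gene drops for the kinship
  oracle) were chosen as the smallest sizes at which each property is
  informative.
* Dominance, epistasis, X-linkage, genotype-based relationship matrices,
  multivariate genetic correlations and household variance components are
  out of scope.
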