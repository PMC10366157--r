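#' Configuration for the synthetic family-data generator
#'
#' Bundles and validates the generative parameters. The defaults emulate a
#' multi-generation adult cohort: a mix of singletons and 2-3-generation
#' pedigrees with sibships of 1-6 children (mean family size about 3.2,
#' families capped at 32 members), an additive-genetic trait component, a
#' couple-shared environmental component, phenotypic assortative mating at
#' couple formation, FFQ-like positive serving counts, and reported energy
#' intakes of which a small fraction are misreported outside the
#' 800-4200 kcal/day plausibility window.
#'
#' @param nFamilies Number of families (a singleton counts as a family).
#' @param generations 2 (nuclear) or 3 (children may marry in a founder
#'   spouse and have children of their own).
#' @param singletonProb Probability a family is a lone individual.
#' @param sibshipDist Probabilities of 1..6 children per couple (sums to 1).
#' @param marryProb With 3 generations, probability each child founds a
#'   third-generation nuclear family.
#' @param maxFamilySize Hard cap on members per family (default 32).
#' @param h2 True narrow-sense heritability of the latent trait in [0, 1].
#' @param c2 Couple-shared environment proportion in [0, 1]; shared by the
#'   two members of each couple, inherited by nobody.
#' @param spousalR Phenotypic assortment: correlation imposed on the
#'   residual components of the two members of a couple, in [0, 1).
#' @param ageEffect Latent-trait slope per year of age (SD units/year).
#' @param sexEffect Latent-trait mean shift for males (SD units).
#' @param energyMean,energySd Reported energy intake model (kcal/day).
#' @param misreportRate Fraction of individuals whose reported energy is
#'   pushed outside the 800-4200 window (default 668/10468).
#' @param traits Names of the food variables to generate (independent latent
#'   traits sharing the same generative parameters).
#' @param servingsLogMean,servingsLogSd Log-scale location and scale of the
#'   exponential back-transform from latent trait to servings per 1000 kcal.
#' @param seed Integer seed.
#' @return A validated list of class \code{"famaggSimConfig"}.
#' @export
simulationConfig <- function(nFamilies = 200, generations = 3,
                             singletonProb = 0.36,
                             sibshipDist = c(0.60, 0.25, 0.08, 0.04, 0.02, 0.01),
                             marryProb = 0.25, maxFamilySize = 32,
                             h2 = 0.25, c2 = 0.15, spousalR = 0.2,
                             ageEffect = 0.01, sexEffect = 0.2,
                             energyMean = 2300, energySd = 500,
                             misreportRate = 668 / 10468,
                             traits = "food_group_1",
                             servingsLogMean = log(0.9),
                             servingsLogSd = 0.35, seed = 1L) {
  cfg <- list(nFamilies = as.integer(nFamilies),
              generations = as.integer(generations),
              singletonProb = singletonProb,
              sibshipDist = sibshipDist, marryProb = marryProb,
              maxFamilySize = as.integer(maxFamilySize),
              h2 = h2, c2 = c2, spousalR = spousalR,
              ageEffect = ageEffect, sexEffect = sexEffect,
              energyMean = energyMean, energySd = energySd,
              misreportRate = misreportRate, traits = traits,
              servingsLogMean = servingsLogMean,
              servingsLogSd = servingsLogSd, seed = as.integer(seed))
  if (!cfg$generations %in% c(2L, 3L)) stop("generations must be 2 or 3")
  if (abs(sum(cfg$sibshipDist) - 1) > 1e-8)
    stop("sibshipDist must sum to 1")
  if (length(cfg$sibshipDist) != 6)
    stop("sibshipDist must give probabilities for sibships of 1..6")
  if (cfg$h2 < 0 || cfg$c2 < 0 || cfg$h2 + cfg$c2 > 1)
    stop("need h2 >= 0, c2 >= 0 and h2 + c2 <= 1")
  if (cfg$spousalR < 0 || cfg$spousalR >= 1)
    stop("spousalR must be in [0, 1)")
  if (cfg$misreportRate < 0 || cfg$misreportRate >= 1)
    stop("misreportRate must be in [0, 1)")
  class(cfg) <- "famaggSimConfig"
  cfg
}

#' Simulate pedigrees
#'
#' Draws \code{nFamilies} families: with probability \code{singletonProb} a
#' lone founder; otherwise a founder couple with a sibship drawn from
#' \code{sibshipDist}; with 3 generations each child may (probability
#' \code{marryProb}) marry a new founder and have a sibship of its own,
#' subject to \code{maxFamilySize}. Sexes are Bernoulli(0.5) except
#' married-in spouses, who take the opposite sex.
#'
#' @param cfg A [simulationConfig()].
#' @param seed Seed override (default \code{cfg$seed}).
#' @return A [Pedigree-class].
#' @export
simulatePedigrees <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "famaggSimConfig"))
  set.seed(seed)
  rows <- vector("list", cfg$nFamilies)
  for (f in seq_len(cfg$nFamilies)) {
    fid <- sprintf("FAM%05d", f)
    k <- 0L
    nid <- function() { k <<- k + 1L; sprintf("%s_I%02d", fid, k) }
    fam <- list()
    addRow <- function(iid, pat, mat, sex)
      fam[[length(fam) + 1L]] <<- data.frame(
        fid = fid, iid = iid, pat = pat, mat = mat, sex = sex,
        stringsAsFactors = FALSE)
    if (stats::runif(1) < cfg$singletonProb) {
      addRow(nid(), NA, NA, sample(c("male", "female"), 1))
    } else {
      dad <- nid(); mum <- nid()
      addRow(dad, NA, NA, "male"); addRow(mum, NA, NA, "female")
      nKids <- sample(1:6, 1, prob = cfg$sibshipDist)
      kids <- character(nKids)
      for (c_ in seq_len(nKids)) {
        kids[c_] <- nid()
        addRow(kids[c_], dad, mum, sample(c("male", "female"), 1))
      }
      if (cfg$generations == 3L) {
        size <- function() length(fam)
        for (kid in sample(kids)) {
          if (stats::runif(1) >= cfg$marryProb) next
          nGkids <- sample(1:6, 1, prob = cfg$sibshipDist)
          if (size() + 1L + nGkids > cfg$maxFamilySize) next
          kidSex <- fam[[match(kid, vapply(fam, `[[`, "", "iid"))]]$sex
          spouse <- nid()
          addRow(spouse, NA, NA, if (kidSex == "male") "female" else "male")
          pat <- if (kidSex == "male") kid else spouse
          mat <- if (kidSex == "male") spouse else kid
          for (g in seq_len(nGkids))
            addRow(nid(), pat, mat, sample(c("male", "female"), 1))
        }
      }
    }
    rows[[f]] <- do.call(rbind, fam)
  }
  pedigree(do.call(rbind, rows))
}

# couples (father, mother) with at least one common child
.couples <- function(p) {
  unique(p[!is.na(p$pat) & !is.na(p$mat), c("pat", "mat")])
}

#' Simulate phenotypes on a pedigree
#'
#' Generates, per trait, a latent value
#' \deqn{\ell_i = \beta_{age}(age_i - \bar{age}) + \beta_{sex}\,[sex_i =
#' male] + g_i + c_i + e_i}
#' with \eqn{g \sim N(0, 2\phi\, h^2)} (family-block Cholesky of the
#' additive relationship matrix), \eqn{c} a couple-shared environmental
#' effect of variance \eqn{c^2} (members of a couple share one draw;
#' everyone else gets an independent one), and \eqn{e} residual with
#' variance \eqn{1 - h^2 - c^2}; the two residuals of a couple are drawn
#' bivariate-normal with correlation \code{spousalR} (phenotypic assortment
#' at couple formation). Ages decrease by generation around a plausible
#' adult-cohort range; reported energy comes from the energy model with a
#' \code{misreportRate} fraction pushed strictly outside 800-4200 kcal/day.
#' Observed servings/day are the exponential back-transform
#' \eqn{\exp(\mu_s + \sigma_s \ell_i) \cdot energy_i / 1000}, so the raw
#' table is positive and right-skewed like FFQ serving counts.
#'
#' @param ped A [Pedigree-class], typically from [simulatePedigrees()].
#' @param cfg A [simulationConfig()].
#' @param seed Seed override (default \code{cfg$seed + 1}).
#' @return A raw-state [PhenotypeTable-class]; besides the trait columns it
#'   carries \code{fid} and one \code{latent_<trait>} column per trait (the
#'   noiseless generative scale, useful for oracle checks; not part of
#'   [traitNames()]).
#' @export
simulatePhenotypes <- function(ped, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "famaggSimConfig"))
  set.seed(seed)
  p <- pedTable(ped)
  n <- nrow(p)
  age <- pmax(18, 68 - 26 * p$generation + stats::rnorm(n, 0, 5))
  sexMale <- as.numeric(p$sex == "male")

  # energy with misreporting outside the plausibility window
  energy <- pmin(pmax(stats::rnorm(n, cfg$energyMean, cfg$energySd), 850), 4150)
  bad <- stats::runif(n) < cfg$misreportRate
  lowHigh <- stats::runif(n) < 0.5
  energy[bad & lowHigh] <- stats::runif(sum(bad & lowHigh), 350, 795)
  energy[bad & !lowHigh] <- stats::runif(sum(bad & !lowHigh), 4205, 5600)

  # family-block Cholesky factors of A = 2*phi
  blocks <- lapply(split(p, p$fid), function(pf) {
    A <- 2 * .kinshipBlock(pf)
    diag(A) <- diag(A) + 1e-10
    list(ids = rownames(A), L = chol(A))
  })
  cp <- .couples(p)
  idx <- stats::setNames(seq_len(n), p$iid)
  sigmaE2 <- 1 - cfg$h2 - cfg$c2

  d <- data.frame(individual_id = p$iid, fid = p$fid, age = age,
                  sex = p$sex, energy = energy, stringsAsFactors = FALSE)
  for (tr in cfg$traits) {
    g <- numeric(n)
    if (cfg$h2 > 0) {
      for (b in blocks) {
        z <- stats::rnorm(length(b$ids))
        g[idx[b$ids]] <- sqrt(cfg$h2) * drop(crossprod(b$L, z))
      }
    }
    cc <- stats::rnorm(n, 0, sqrt(cfg$c2))
    e <- stats::rnorm(n, 0, sqrt(max(sigmaE2, 0)))
    if (nrow(cp)) {
      i1 <- idx[cp$pat]; i2 <- idx[cp$mat]
      cc[i2] <- cc[i1]                     # shared couple environment
      if (cfg$spousalR > 0 && sigmaE2 > 0) {
        r <- cfg$spousalR
        e2new <- r * e[i1] + sqrt(1 - r^2) * e[i2]
        e[i2] <- e2new                     # assortment on residuals
      }
    }
    latent <- cfg$ageEffect * (age - mean(age)) + cfg$sexEffect * sexMale +
      g + cc + e
    servingsPer1000 <- exp(cfg$servingsLogMean + cfg$servingsLogSd * latent)
    d[[tr]] <- servingsPer1000 * energy / 1000
    d[[paste0("latent_", tr)]] <- latent
  }
  phenotypeTable(d, traits = cfg$traits)
}

#' Simulate a complete synthetic study
#'
#' @param cfg A [simulationConfig()].
#' @return List with \code{pedigree}, \code{phenotypes} (raw
#'   [PhenotypeTable-class]) and \code{truth} (the generative parameters).
#' @export
simulateStudy <- function(cfg = simulationConfig()) {
  ped <- simulatePedigrees(cfg)
  pt <- simulatePhenotypes(ped, cfg)
  list(pedigree = ped, phenotypes = pt,
       truth = unclass(cfg))
}

#' Write a simulated study to disk
#'
#' Writes \code{<prefix>.ped} (PLINK-style pedigree), \code{<prefix>.csv}
#' (raw phenotypes) and \code{<prefix>_truth.json} (generative parameters).
#'
#' @param sim Output of [simulateStudy()].
#' @param prefix Path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
writeSimulation <- function(sim, prefix) {
  pedPath <- paste0(prefix, ".ped")
  csvPath <- paste0(prefix, ".csv")
  truthPath <- paste0(prefix, "_truth.json")
  writePedigree(sim$pedigree, pedPath)
  utils::write.csv(phenoData(sim$phenotypes), csvPath, row.names = FALSE)
  jsonlite::write_json(sim$truth, truthPath, auto_unbox = TRUE, digits = NA)
  invisible(c(pedPath, csvPath, truthPath))
}
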