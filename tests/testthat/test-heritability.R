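# small simulated dataset shared by several blocks
simDataset <- function(nFamilies, h2, seed, c2 = 0, spousalR = 0) {
  cfg <- simulationConfig(nFamilies = nFamilies, generations = 2,
                          singletonProb = 0, h2 = h2, c2 = c2,
                          spousalR = spousalR, ageEffect = 0.01,
                          sexEffect = 0.2, misreportRate = 0, seed = seed)
  ped <- simulatePedigrees(cfg)
  pt <- simulatePhenotypes(ped, cfg)
  d <- phenoData(pt)
  kin <- kinshipMatrix(ped)
  ids <- individualIds(kin)
  d <- d[match(ids, d$individual_id), ]
  list(y = d$latent_food_group_1,
       X = cbind(intercept = 1, age = d$age,
                 sex = as.numeric(d$sex == "male")),
       A = relationshipMatrix(kin), d = d, kin = kin, pt = pt, ped = ped)
}

test_that("retained-draw count follows the floor formula", {
  expect_identical(retainedDraws(400000, 200000, 40), 5000L)
  expect_identical(retainedDraws(1000, 500, 7), 71L)
  expect_error(retainedDraws(100, 100, 1), "below")
})

test_that("a short run retains exactly the predicted number of draws", {
  s <- simDataset(30, 0.3, seed = 4)
  fit <- fitGaussianMCMC(s$y, s$X, s$A, nIter = 2000, nBurnin = 900,
                         thin = 7, nChains = 2, seed = 2)
  expect_identical(fit@nRetained, retainedDraws(2000, 900, 7))
  expect_equal(nrow(posteriorDraws(fit)), 2L * fit@nRetained)
})

test_that("h2 draws stay in [0,1] and variance draws nonnegative", {
  s <- simDataset(40, 0.4, seed = 8)
  fit <- fitGaussianMCMC(s$y, s$X, s$A, nIter = 1500, nBurnin = 500,
                         thin = 2, nChains = 2, seed = 5)
  dr <- posteriorDraws(fit)
  expect_true(all(dr$h2 >= 0 & dr$h2 <= 1))
  expect_true(all(dr$sigma_g2 > 0) && all(dr$sigma_e2 > 0))
  expect_true(all(rhat(fit) >= 1 - 1e-8, na.rm = TRUE))
})

test_that("same seed reproduces draws exactly; shifted y moves only the intercept", {
  s <- simDataset(25, 0.3, seed = 12)
  f1 <- fitGaussianMCMC(s$y, s$X, s$A, nIter = 800, nBurnin = 300,
                        thin = 5, nChains = 2, seed = 99)
  f2 <- fitGaussianMCMC(s$y, s$X, s$A, nIter = 800, nBurnin = 300,
                        thin = 5, nChains = 2, seed = 99)
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))

  m1 <- fitGaussianML(s$y, s$X, s$A)
  m2 <- fitGaussianML(s$y + 10, s$X, s$A)
  expect_equal(m1$sigma_g2, m2$sigma_g2, tolerance = 1e-6)
  expect_equal(m1$sigma_e2, m2$sigma_e2, tolerance = 1e-6)
  expect_equal(m2$beta[["intercept"]] - m1$beta[["intercept"]], 10,
               tolerance = 1e-6)
})

test_that("Gibbs posterior matches exact numerical integration", {
  # strong correctness check: the marginal posterior of (sigma_g2, sigma_e2)
  # is computed by brute-force 2-D quadrature with beta integrated out, and
  # the sampler must reproduce its h2 mean
  s <- simDataset(40, 0.3, seed = 500)
  exact <- oracleExactPosteriorH2(s$y, s$X, s$A, nu = 5)
  fit <- fitGaussianMCMC(s$y, s$X, s$A, nIter = 20000, nBurnin = 10000,
                         thin = 5, nChains = 2, seed = 7, priorDf = 5)
  expect_lt(abs(h2Mean(fit) - exact), 0.02)
})

test_that("block-diagonal and dense relationship inputs agree", {
  cfg <- simulationConfig(nFamilies = 25, h2 = 0.4, c2 = 0,
                          misreportRate = 0, seed = 9)
  ped <- simulatePedigrees(cfg)
  pt <- simulatePhenotypes(ped, cfg)
  d <- phenoData(pt)
  kin <- kinshipMatrix(ped)
  rb <- relationshipBlocks(ped)
  expect_identical(attr(rb, "ids"), individualIds(kin))
  d <- d[match(individualIds(kin), d$individual_id), ]
  y <- d$latent_food_group_1
  X <- cbind(intercept = 1, age = d$age, sex = as.numeric(d$sex == "male"))
  m1 <- fitGaussianML(y, X, relationshipMatrix(kin))
  m2 <- fitGaussianML(y, X, rb)
  expect_equal(m1$h2, m2$h2, tolerance = 1e-6)
  expect_equal(m1$loglik, m2$loglik, tolerance = 1e-8)
})

test_that("probit link: latent liability machinery matches Phi at eta = 0 and flags degenerate input", {
  expect_equal(pnorm(0), 0.5)   # the link identity the sampler relies on
  s <- simDataset(20, 0.3, seed = 44)
  expect_error(fitProbitMCMC(rep(1, length(s$y)), s$X, s$A),
               "degenerate_response")
  expect_error(fitProbitMCMC(s$y, s$X, s$A), "0/1")
})

# binary data carry about half the information of the Gaussian trait, so the
# boundary-skewed posterior mean needs a large cohort before it can sit near
# the generative value; these run at multi-thousand-family scale
cohortDataset <- function(nFamilies, h2, seed) {
  cfg <- simulationConfig(nFamilies = nFamilies, h2 = h2, c2 = 0,
                          spousalR = 0, ageEffect = 0.01, sexEffect = 0.2,
                          misreportRate = 0, seed = seed)
  ped <- simulatePedigrees(cfg)
  pt <- simulatePhenotypes(ped, cfg)
  d <- phenoData(pt)
  rb <- relationshipBlocks(ped)
  d <- d[match(attr(rb, "ids"), d$individual_id), ]
  list(y = d$latent_food_group_1,
       X = cbind(intercept = 1, age = d$age,
                 sex = as.numeric(d$sex == "male")),
       A = rb)
}

test_that("probit recovery: thresholded liability h2 is recovered within 0.12", {
  s <- cohortDataset(2000, 0.4, seed = 77)
  yb <- as.numeric(s$y > median(s$y))
  fit <- fitProbitMCMC(yb, s$X, s$A, nIter = 5000, nBurnin = 2500,
                       thin = 5, nChains = 1, seed = 3)
  expect_lt(abs(h2Mean(fit) - 0.4), 0.12)
  expect_true(all(posteriorDraws(fit)$sigma_e2 == 1))
})

test_that("probit null: posterior mean h2 stays small", {
  s <- cohortDataset(4338, 0, seed = 55)
  yb <- as.numeric(s$y > median(s$y))
  fit <- fitProbitMCMC(yb, s$X, s$A, nIter = 4000, nBurnin = 2000,
                       thin = 4, nChains = 1, seed = 9)
  expect_lt(h2Mean(fit), 0.12)
})

test_that("ML arm flags a flat likelihood when everyone is unrelated", {
  withr::with_seed(60, {
    n <- 120
    y <- rnorm(n)
    ml <- fitGaussianML(y, NULL, diag(n))
    expect_true(ml$flat_likelihood)
    expect_true(is.na(ml$h2))
  })
})

test_that("ML profile optimum beats a 200-point grid oracle on a small pedigree", {
  s <- simDataset(12, 0.5, seed = 31)     # ~40 individuals, fixed data
  expect_gte(length(s$y), 35)
  ml <- fitGaussianML(s$y, s$X, s$A)
  rhos <- seq(0, 0.995, length.out = 200)
  gl <- oracleLoglikGrid(s$y, s$X, s$A, rhos)
  expect_gte(ml$loglik, max(gl) - 1e-6)
  # and the profiled loglik agrees with the dense-matrix likelihood
  expect_equal(ml$loglik_null, gl[1], tolerance = 1e-6)
})

test_that("Gibbs and ML arms agree on a moderate simulated dataset", {
  s <- simDataset(150, 0.35, seed = 19)
  ml <- fitGaussianML(s$y, s$X, s$A)
  fit <- fitGaussianMCMC(s$y, s$X, s$A, nIter = 5000, nBurnin = 2500,
                         thin = 5, nChains = 1, seed = 7)
  expect_lt(abs(ml$h2 - h2Mean(fit)), 0.05)
})

test_that("split Gelman-Rubin matches its definition and conventions", {
  expect_error(gelmanRubin(list(rnorm(100))), "at least 2")
  expect_error(gelmanRubin(list(rnorm(100), rnorm(50))), "equal length")
  expect_error(gelmanRubin(list(rnorm(5), rnorm(5))), "length >= 10")
  expect_equal(gelmanRubin(list(rep(1, 50), rep(1, 50))), 1)

  withr::with_seed(13, {
    sep <- list(rnorm(1000, 0), rnorm(1000, 5))
    expect_gt(gelmanRubin(sep), 1.5)
    expect_equal(gelmanRubin(sep), oracleSplitRhat(sep), tolerance = 1e-12)

    mixed <- lapply(1:3, function(i) rnorm(500))
    expect_equal(gelmanRubin(mixed), oracleSplitRhat(mixed),
                 tolerance = 1e-12)
  })
})

test_that("iid chains give Rhat below 1.01 nearly always", {
  withr::with_seed(17, {
    ok <- 0L
    for (r in 1:100) {
      ch <- lapply(1:4, function(i) rnorm(2000))
      if (gelmanRubin(ch) < 1.01) ok <- ok + 1L
    }
    expect_gte(ok, 95L)
  })
})

test_that("fitHeritability wraps prep output, kinship and both arms", {
  cfg <- simulationConfig(nFamilies = 60, generations = 2,
                          singletonProb = 0, h2 = 0.4, c2 = 0,
                          misreportRate = 0, seed = 23)
  sim <- simulateStudy(cfg)
  pt <- prepareTraits(energyAdjust(filterEnergy(sim$phenotypes)))
  kin <- kinshipMatrix(sim$pedigree)
  fit <- fitHeritability(pt, kin, "food_group_1", arm = "both",
                         nIter = 1500, nBurnin = 700, thin = 4,
                         nChains = 2, seed = 2)
  expect_s4_class(fit, "HeritabilityFit")
  expect_true(length(mlEstimate(fit)) > 0)
  tab <- heritabilityTable(fit, "food_group_1")
  expect_equal(tab$h2_percent, 100 * h2Mean(fit))
  expect_true(tab$n_retained == fit@nRetained)
})
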