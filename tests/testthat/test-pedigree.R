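test_that("reading a trio file yields 2 founders and 1 non-founder", {
  for (variant in list(list(sep = " ", header = FALSE),
                       list(sep = ",", header = TRUE))) {
    path <- writePedFile(trioDf(), sep = variant$sep,
                         header = variant$header)
    ped <- readPedigree(path)
    expect_s4_class(ped, "Pedigree")
    expect_equal(nIndividuals(ped), 3L)
    expect_setequal(founders(ped), c("dad", "mum"))
    expect_equal(pedTable(ped)$generation[match("kid", individualIds(ped))],
                 1L)
  }
})

test_that("pedigree validation rejects bad structures", {
  bad <- trioDf()
  bad$sex[bad$iid == "mum"] <- "male"
  expect_error(pedigree(bad), "sex-inconsistent")

  dup <- rbind(trioDf(), trioDf()[3, ])
  expect_error(pedigree(dup), "duplicate")

  cyc <- data.frame(fid = "C", iid = c("a", "b"), pat = c("b", "a"),
                    mat = NA, sex = "male")
  expect_error(pedigree(cyc), "cycle")
})

test_that("parents referenced but not listed become founders", {
  df <- data.frame(fid = "F", iid = "kid", pat = "ghostdad",
                   mat = "ghostmum", sex = "2")
  ped <- pedigree(df)
  expect_equal(nIndividuals(ped), 3L)
  expect_setequal(founders(ped), c("ghostdad", "ghostmum"))
  p <- pedTable(ped)
  expect_equal(p$sex[p$iid == "ghostdad"], "male")
  expect_equal(p$sex[p$iid == "ghostmum"], "female")
})

test_that("a 32-member synthetic family parses with the right size range", {
  # couple + 6 children, each child marries in a spouse and the six
  # sibships of the third generation total 18: 2 + 6 + 6 + 18 = 32
  kidSizes <- c(4, 4, 3, 3, 2, 2)
  rows <- list(data.frame(fid = "BIG", iid = c("p1", "p2"), pat = NA,
                          mat = NA, sex = c("male", "female")))
  for (k in 1:6) {
    kid <- sprintf("k%d", k); sp <- sprintf("s%d", k)
    rows[[length(rows) + 1L]] <- data.frame(
      fid = "BIG", iid = c(kid, sp), pat = c("p1", NA), mat = c("p2", NA),
      sex = c("male", "female"))
    rows[[length(rows) + 1L]] <- data.frame(
      fid = "BIG", iid = sprintf("g%d_%d", k, seq_len(kidSizes[k])),
      pat = kid, mat = sp, sex = "male")
  }
  df <- do.call(rbind, rows)
  ped <- readPedigree(writePedFile(df))
  expect_equal(nIndividuals(ped), 32L)
  expect_equal(max(pedTable(ped)$generation), 2L)

  # the simulator respects the same cap
  cfg <- simulationConfig(nFamilies = 40, singletonProb = 0,
                          sibshipDist = c(0, 0, 0, 0, 0, 1),
                          marryProb = 1, maxFamilySize = 32, seed = 11)
  expect_lte(max(table(pedTable(simulatePedigrees(cfg))$fid)), 32)
})

test_that("trio and nuclear-family pair classification matches combinatorics", {
  trio <- pedigree(trioDf())
  prs <- classifyPairs(trio)
  expect_equal(nrow(prs), 3L)
  expect_setequal(prs$pair_class,
                  c("father-daughter", "mother-daughter", "spouse"))

  nuc <- pedigree(nuclearDf())
  prs <- classifyPairs(nuc)
  cnt <- table(prs$pair_class)
  expect_equal(unname(cnt[["sister-sister"]]), 1L)
  expect_equal(unname(cnt[["brother-sister"]]), 2L)
  expect_equal(unname(cnt[["spouse"]]), 1L)
  po <- sum(cnt[c("father-son", "father-daughter", "mother-son",
                  "mother-daughter")])
  expect_equal(po, 6L)
})

test_that("extended pedigree yields second-degree classes with senior role first", {
  ped <- pedigree(extendedDf())
  prs <- classifyPairs(ped)
  key <- stats::setNames(prs$pair_class, paste(prs$id_a, prs$id_b))
  expect_equal(unname(key[["gpa c1"]]), "grandparent")
  expect_equal(unname(key[["aunt c1"]]), "avuncular")
  expect_equal(unname(key[["c1 c2"]]), "cousin")
  expect_equal(unname(key[["c1 h1"]]), "half-sibling")
  # every pair appears at most once: the classification is a partition
  expect_false(any(duplicated(t(apply(prs[, c("id_a", "id_b")], 1, sort)))))
})

test_that("pair classification equals the ancestor-path oracle on simulated families", {
  cfg <- simulationConfig(nFamilies = 60, seed = 21)
  ped <- simulatePedigrees(cfg)
  prs <- classifyPairs(ped)
  got <- table(factor(prs$pair_class, levels = pairClasses()))
  want <- oracleClassify(ped)
  expect_equal(as.integer(got[pairClasses()]),
               as.integer(want[pairClasses()]))
})

test_that("classic kinship coefficients are exact", {
  ped <- pedigree(extendedDf())
  phi <- kinshipCoefficients(kinshipMatrix(ped))
  expect_equal(phi["f1", "c1"], 0.25)        # parent-offspring
  expect_equal(phi["f1", "f2"], 0.25)        # full sibs
  expect_equal(phi["c1", "h1"], 0.125)       # half sibs
  expect_equal(phi["gpa", "c1"], 0.125)      # grandparent
  expect_equal(phi["aunt", "c1"], 0.125)     # avuncular
  expect_equal(phi["c1", "c2"], 0.0625)      # first cousins
  expect_equal(phi["gpa", "gma"], 0)         # unrelated spouses
  expect_equal(unname(diag(phi)), rep(0.5, nrow(phi)))
})

test_that("child of first cousins has f = 0.0625 and phi_self = 0.53125", {
  df <- extendedDf()
  inbred <- rbind(df, data.frame(fid = "E1", iid = "z", pat = "c1",
                                 mat = "c2", sex = "male"))
  kin <- kinshipMatrix(pedigree(inbred))
  expect_equal(unname(inbreeding(kin)["z"]), 0.0625)
  expect_equal(kinshipCoefficients(kin)["z", "z"], 0.53125)
})

test_that("kinship is symmetric, within [0,1], and A is PSD after jitter", {
  cfg <- simulationConfig(nFamilies = 30, seed = 5)
  kin <- kinshipMatrix(simulatePedigrees(cfg))
  phi <- kinshipCoefficients(kin)
  expect_identical(phi, t(phi))
  expect_true(all(phi >= 0 & phi <= 1))
  A <- relationshipMatrix(kin)
  expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("kinship agrees with pair classes on non-inbred pedigrees", {
  cfg <- simulationConfig(nFamilies = 40, seed = 31)
  ped <- simulatePedigrees(cfg)
  phi <- kinshipCoefficients(kinshipMatrix(ped))
  prs <- classifyPairs(ped)
  phiOf <- phi[cbind(prs$id_a, prs$id_b)]
  first <- prs$pair_class %in% c("father-son", "father-daughter",
                                 "mother-son", "mother-daughter",
                                 "sister-sister", "brother-brother",
                                 "brother-sister")
  expect_true(all(phiOf[first] == 0.25))
  second <- prs$pair_class %in% c("grandparent", "avuncular", "half-sibling")
  expect_true(all(phiOf[second] == 0.125))
  expect_true(all(phiOf[prs$pair_class == "cousin"] == 0.0625))
  expect_true(all(phiOf[prs$pair_class == "spouse"] == 0))
})

test_that("matrix and pair list are invariant to input row order", {
  df <- extendedDf()
  withr::with_seed(1, perm <- df[sample(nrow(df)), ])
  k1 <- kinshipCoefficients(kinshipMatrix(pedigree(df)))
  k2 <- kinshipCoefficients(kinshipMatrix(pedigree(perm)))
  expect_identical(k1, k2)
  p1 <- classifyPairs(pedigree(df))
  p2 <- classifyPairs(pedigree(perm))
  expect_identical(p1[order(p1$id_a, p1$id_b), ],
                   p2[order(p2$id_a, p2$id_b), ],
                   ignore_attr = TRUE)
  expect_equal(p1[order(p1$id_a, p1$id_b), ]$pair_class,
               p2[order(p2$id_a, p2$id_b), ]$pair_class)
})

test_that("kinship export round-trips in long and matrix form", {
  kin <- kinshipMatrix(pedigree(nuclearDf()))
  longPath <- withr::local_tempfile(fileext = ".csv")
  writeKinship(kin, longPath, "long")
  lg <- read.csv(longPath)
  expect_equal(nrow(lg), 5 * 6 / 2)
  expect_equal(lg$phi[lg$id_a == "g1" & lg$id_b == "g2"], 0.25)
  matPath <- withr::local_tempfile(fileext = ".csv")
  writeKinship(kin, matPath, "matrix")
  mt <- read.csv(matPath, check.names = FALSE)
  expect_equal(as.matrix(mt[, -1]), kinshipCoefficients(kin),
               ignore_attr = TRUE)
})
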