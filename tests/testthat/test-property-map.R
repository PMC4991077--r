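test_that("property standardization follows the documented sample-sd convention", {
  z <- standardizeProperty(c(1, 2, 3), log_transform = FALSE)
  expect_equal(as.numeric(z), c(-1, 0, 1))   # sample sd = 1 for {1,2,3}
  expect_error(standardizeProperty(c(2, 2, 2), log_transform = FALSE),
               "constant property")
  # affine invariance
  x <- c(3, 9, 1, 7, 5)
  z1 <- as.numeric(standardizeProperty(x, log_transform = FALSE))
  z2 <- as.numeric(standardizeProperty(2.5 * x + 7, log_transform = FALSE))
  expect_equal(z1, z2, tolerance = 1e-12)
  # heavy-tailed properties are logged by default
  zv <- standardizeProperty(c(10, 100, 1000), "viscosity")
  expect_true(attr(zv, "logged"))
  expect_equal(as.numeric(zv), c(-1, 0, 1))
  expect_error(standardizeProperty(c(-1, 2, 3), "viscosity"), "positive")
})

test_that("binning is half-open with boundary values in the upper bin", {
  b <- binToLevels(0)
  expect_equal(b$bin, 2L)           # middle of 5 bins
  expect_identical(b$level, "medium")
  # a value exactly on an edge belongs to the upper of the adjacent bins
  eps <- 1e-9
  edge <- -0.5
  expect_equal(binToLevels(edge)$bin, binToLevels(edge + eps)$bin)
  expect_equal(binToLevels(edge - eps)$bin, binToLevels(edge)$bin - 1L)
  # clamping beyond the outer edges
  expect_equal(binToLevels(99)$bin, 4L)
  expect_equal(binToLevels(-99)$bin, 0L)
  expect_identical(binToLevels(99)$level, "very-high")
  expect_error(binToLevels(0, edges = c(1, 1, 2)), "strictly increasing")
})

test_that("trend rules have the documented signs and zero point", {
  expect_equal(unname(trendScores(c(0, 0))[1, ]), rep(0, 4))
  t1 <- trendScores(c(1, 0)); t2 <- trendScores(c(2, 0))
  # increasing PC1 at fixed PC2: Kow up, solubility down
  expect_gt(t2[, "Kow"], t1[, "Kow"])
  expect_lt(t2[, "solubility"], t1[, "solubility"])
  # decreasing PC2 at fixed PC1: viscosity strictly up
  pc2 <- seq(3, -3, length.out = 7)
  tv <- trendScores(cbind(PC1 = 1, PC2 = pc2))[, "viscosity"]
  expect_true(all(diff(tv) > 0))
  # enthalpy of fusion follows PC2 alone
  expect_equal(unname(trendScores(c(5, 2))[, "enthalpy_of_fusion"]),
               2)
})

test_that("qualitative levels come from training percentiles with cluster notes", {
  set.seed(8)
  training <- as.data.frame(matrix(rnorm(50 * 4), 50, 4))
  names(training) <- c("viscosity", "Kow", "solubility", "enthalpy_of_fusion")
  # an IL at the training maximum of T_Kow is "high"
  q <- qualitativePredict(
    trend = matrix(c(0, max(training$Kow), 0, 0), 1,
                   dimnames = list(NULL, names(training))),
    training_trend = training, cluster = "B", scores = matrix(c(0, 0), 1))
  expect_identical(q$Kow_level, "high")
  expect_equal(q$Kow_percentile, 1)
  # cluster heuristics for the enthalpy of fusion
  qa <- qualitativePredict(matrix(0, 1, 4, dimnames = list(NULL, names(training))),
                           training, "A", matrix(c(-1, 0), 1))
  expect_identical(qa$dhf_cluster_note, "low-prone")
  qc <- qualitativePredict(matrix(0, 1, 4, dimnames = list(NULL, names(training))),
                           training, "C", matrix(c(-1, 2), 1))
  expect_identical(qc$dhf_cluster_note, "high-prone")
  expect_match(qc$visc_note, "lowest viscosities")
  expect_match(qc$dhf_confidence, "reduced confidence")
  # solubility caveat flags high-PC1 queries
  qh <- qualitativePredict(matrix(0, 1, 4, dimnames = list(NULL, names(training))),
                           training, "E", matrix(c(3, 0), 1))
  expect_true(qh$sol_caveat_high_pc1)
  expect_false(qa$sol_caveat_high_pc1)
  expect_error(qualitativePredict(matrix(0, 1, 4), training[0, ], "A",
                                  matrix(c(0, 0), 1)),
               "empty training")
})

test_that("levels are monotone in the trend score", {
  set.seed(15)
  training <- as.data.frame(matrix(rnorm(40 * 4), 40, 4))
  names(training) <- c("viscosity", "Kow", "solubility", "enthalpy_of_fusion")
  pc1 <- seq(-3, 3, length.out = 9)
  tr <- trendScores(cbind(PC1 = pc1, PC2 = 0))
  q <- qualitativePredict(tr, training, rep("B", 9),
                          cbind(pc1, 0))
  ord <- c(low = 1, medium = 2, high = 3)
  expect_true(all(diff(ord[q$Kow_level]) >= 0))
  expect_true(all(diff(ord[q$solubility_level]) <= 0))
})

test_that("trend scores track the synthetic property values on the fixture set", {
  ref <- fixture_reference()
  b <- fixture_bundle()
  sc <- trainingScores(b)
  tr <- trendScores(sc, b@overlays$weights)
  for (p in c("viscosity", "Kow", "solubility", "enthalpy_of_fusion")) {
    sub <- ref$properties[ref$properties$property == p, ]
    v <- sub$value[match(rownames(sc), sub$il_id)]
    rho <- cor(tr[, p], v, method = "spearman")
    expect_gt(rho, 0.5)
  }
})
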