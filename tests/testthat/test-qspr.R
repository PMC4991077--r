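planted_data <- function(n = 20, p = 10, seed = 2, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", seq_len(p))))
  j <- min(7L, p)
  y <- 3 + 2 * X[, 2] - 1.5 * X[, j] + rnorm(n, 0, noise)
  list(X = X, y = y, true_set = paste0("d", c(2L, j)))
}

test_that("the rank split yields 20/10 and 4/2 with extremes in training", {
  rec <- data.frame(il_id = paste0("i", 1:30), value = rnorm(30))
  sp <- splitDataset(rec)
  expect_equal(nrow(sp$training), 20L)
  expect_equal(nrow(sp$validation), 10L)
  expect_lte(max(sp$validation$value), max(sp$training$value))
  expect_gte(min(sp$validation$value), min(sp$training$value))

  rec6 <- data.frame(il_id = paste0("i", 1:6), value = c(5, 1, 3, 9, 7, 2))
  sp6 <- splitDataset(rec6)
  expect_equal(nrow(sp6$training), 4L)
  expect_equal(nrow(sp6$validation), 2L)
  expect_error(splitDataset(rec6[1:5, ]), "at least 6")
})

test_that("MLR recovers a noiseless linear model exactly", {
  x <- seq(0, 9)
  m <- fitMLR(cbind(x = x), 3 + 2 * x)
  expect_equal(unname(modelCoefficients(m)), c(3, 2), tolerance = 1e-10)
  expect_equal(modelStats(m)$r2, 1, tolerance = 1e-12)
  expect_equal(modelStats(m)$q2_loo, 1, tolerance = 1e-10)
})

test_that("R^2 is zero for a response orthogonal to the predictors", {
  X <- cbind(x = c(-1, 1, -1, 1, -1, 1))
  y <- c(-1, -1, 0, 0, 1, 1)          # orthogonal to x and to the intercept
  m <- fitMLR(X, y)
  expect_equal(modelStats(m)$r2, 0, tolerance = 1e-9)
})

test_that("coefficients equal the normal-equation solution on an 8-point case", {
  set.seed(31)
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(8)
  m <- fitMLR(X, y)
  M <- cbind(1, X)
  beta <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(unname(modelCoefficients(m)), unname(drop(beta)),
               tolerance = 1e-9)
})

test_that("a singular design names the collinear column", {
  X <- cbind(a = rnorm(10), b = 1:10)
  X <- cbind(X, c = 2 * X[, "b"])
  expect_error(fitMLR(X, rnorm(10)), "collinear.*c")
})

test_that("LOO shortcut equals explicit refits and an independent lm loop", {
  set.seed(17)
  X <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(10)
  q_short <- q2Loo(X, y, "shortcut")
  q_refit <- q2Loo(X, y, "refit")
  expect_equal(q_short, q_refit, tolerance = 1e-10)
  # independent oracle: n lm() refits
  press <- 0
  d <- data.frame(y = y, X)
  for (i in 1:10) {
    fit <- lm(y ~ a + b, data = d[-i, ])
    press <- press + (y[i] - predict(fit, d[i, ]))^2
  }
  q_lm <- 1 - press / sum((y - mean(y))^2)
  expect_equal(q_short, unname(q_lm), tolerance = 1e-10)
})

test_that("Q2_LOO is 1 on noiseless data and typically negative on pure noise", {
  x <- seq(1, 12)
  expect_equal(q2Loo(cbind(x = x), 5 - 0.7 * x), 1, tolerance = 1e-12)
  set.seed(99)
  qs <- replicate(20, q2Loo(cbind(x = rnorm(40)), rnorm(40)))
  expect_gt(mean(qs <= 0), 0.6)      # reported, never clamped
  expect_true(any(qs < 0))
})

test_that("external validation computes Q2_ext against the training mean", {
  x <- seq(0, 9)
  m <- fitMLR(cbind(x = x), 3 + 2 * x)
  # distinct points on the same noiseless hyperplane predict perfectly
  xv <- c(0.5, 3.3, 8.1)
  m2 <- externalValidation(m, cbind(x = xv), 3 + 2 * xv)
  expect_equal(modelStats(m2)$q2_ext, 1, tolerance = 1e-10)
  expect_equal(modelStats(m2)$rmse_ext, 0, tolerance = 1e-9)
  # literal training rows are rejected as overlap
  expect_error(externalValidation(m, cbind(x = x[1:3]), (3 + 2 * x)[1:3]),
               "overlap")
  # hand 3-point case
  set.seed(1)
  Xt <- cbind(x = rnorm(8)); yt <- rnorm(8)
  mh <- fitMLR(Xt, yt)
  Xv <- cbind(x = c(0.3, -0.8, 1.4)); yv <- c(0.2, -0.5, 1.0)
  mh <- externalValidation(mh, Xv, yv)
  pred <- modelCoefficients(mh)[1] + modelCoefficients(mh)[2] * Xv[, 1]
  q_hand <- 1 - sum((pred - yv)^2) / sum((yv - mean(yt))^2)
  expect_equal(modelStats(mh)$q2_ext, unname(q_hand), tolerance = 1e-12)
})

test_that("a constant model scores Q2_ext <= 0", {
  yt <- rep(5, 8)
  m <- fitMLR(cbind(x = rnorm(8)), yt)
  m <- externalValidation(m, cbind(x = rnorm(4)), c(4, 6, 5.5, 4.5))
  expect_lte(modelStats(m)$q2_ext, 0)
})

test_that("the GA recovers a planted subset and matches exhaustive search", {
  pd <- planted_data(n = 25, p = 10)
  ga <- gaSelect(pd$X, pd$y, 2, population = 30, generations = 25, seed = 4)
  expect_setequal(ga$selected, pd$true_set)
  # exhaustive-subset oracle over all C(10, 2) subsets
  combos <- combn(colnames(pd$X), 2, simplify = FALSE)
  fits <- vapply(combos, function(s) q2Loo(pd$X[, s], pd$y), numeric(1))
  expect_setequal(ga$selected, combos[[which.max(fits)]])
  expect_equal(ga$fitness, max(fits), tolerance = 1e-12)
})

test_that("the GA is reproducible, elitist, and degenerates gracefully", {
  pd <- planted_data(n = 25, p = 12, noise = 0.5)
  g1 <- gaSelect(pd$X, pd$y, 3, population = 20, generations = 10, seed = 7)
  g2 <- gaSelect(pd$X, pd$y, 3, population = 20, generations = 10, seed = 7)
  expect_identical(g1$selected, g2$selected)
  expect_identical(g1$trace, g2$trace)
  # elitism: the trace never decreases and never drops below the initial best
  expect_true(all(diff(g1$trace) >= 0))
  g0 <- gaSelect(pd$X, pd$y, 3, population = 20, generations = 0, seed = 7)
  expect_length(g0$trace, 1L)
  expect_gte(g1$fitness, g0$fitness)
  # parsimony cap
  expect_warning(gaSelect(pd$X, pd$y, 8, population = 10, generations = 2,
                          seed = 1), "parsimony")
})

test_that("leverages obey the hat-matrix identities and flag extrapolation", {
  set.seed(23)
  X <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1 + X[, 1] + rnorm(15, 0, 0.1)
  m <- fitMLR(X, y)
  ad <- applicabilityDomain(m, y_query = y)
  expect_equal(sum(ad$leverage), 3, tolerance = 1e-9)   # p + 1
  expect_true(all(ad$leverage >= 1 / 15 - 1e-12 & ad$leverage <= 1 + 1e-12))
  expect_equal(attr(ad, "h_star"), 3 * 3 / 15)
  # the training centroid has the minimum leverage 1/n
  cen <- matrix(colMeans(X), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(applicabilityDomain(m, cen)$leverage, 1 / 15, tolerance = 1e-12)
  # far extrapolation falls outside
  far <- matrix(c(50, -50), 1, dimnames = list(NULL, c("a", "b")))
  ad_far <- applicabilityDomain(m, far)
  expect_false(ad_far$inside)
  expect_gt(ad_far$leverage, attr(ad, "h_star"))
})

test_that("all statistics are invariant to descriptor column order", {
  pd <- planted_data(n = 18, p = 4)
  m1 <- fitMLR(pd$X[, c("d1", "d2", "d3")], pd$y)
  m2 <- fitMLR(pd$X[, c("d3", "d1", "d2")], pd$y)
  expect_equal(modelStats(m1)$r2, modelStats(m2)$r2, tolerance = 1e-12)
  expect_equal(modelStats(m1)$q2_loo, modelStats(m2)$q2_loo, tolerance = 1e-12)
  expect_equal(modelCoefficients(m1)[c("d1", "d2", "d3")],
               modelCoefficients(m2)[c("d1", "d2", "d3")], tolerance = 1e-12)
})

test_that("estimated coefficients fall within 3 standard errors (recovery suite)", {
  p_ok <- 0
  n_seeds <- 200
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
    beta <- c(1.5, -2)
    y <- 0.5 + drop(X %*% beta) + rnorm(30, 0, 0.8)
    fit <- lm(y ~ X)
    se <- sqrt(diag(vcov(fit)))[2:3]
    m <- fitMLR(X, y)
    est <- modelCoefficients(m)[c("a", "b")]
    if (all(abs(est - beta) <= 3 * se)) p_ok <- p_ok + 1
  }
  expect_gte(p_ok / n_seeds, 0.95)
})

test_that("the full workflow runs on fixture descriptors and exports a Williams plot", {
  ref <- fixture_reference()
  desc <- descriptorTable(ref$ils)
  dhf <- ref$properties[ref$properties$property == "enthalpy_of_fusion",
                        c("il_id", "value")]
  dhf <- dhf[seq_len(30), ]
  res <- qsprWorkflow(desc, dhf, model_size = 3L, seed = 11,
                      population = 25L, generations = 20L)
  expect_s4_class(res$model, "QSPRModel")
  st <- modelStats(res$model)
  expect_true(st$r2 >= 0 && st$r2 <= 1)
  expect_lte(st$q2_loo, st$r2 + 1e-9)
  expect_true(all(c("il_id", "set", "leverage", "inside", "std_residual")
                  %in% names(res$williams)))
  expect_equal(sum(res$williams$set == "training"), 20L)
  expect_equal(sum(res$williams$set == "validation"), 10L)
  tr_lev <- res$williams$leverage[res$williams$set == "training"]
  expect_equal(sum(tr_lev), length(res$model@descriptors) + 1, tolerance = 1e-9)
})
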