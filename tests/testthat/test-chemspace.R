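test_that("autoscale centers, scales, drops constants and validates input", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  sc <- autoscale(X)
  expect_identical(sc$dropped, "b")
  expect_equal(colnames(sc$scaled), c("a", "c"))
  expect_equal(unname(sc$center), c(2, 5))
  expect_equal(unname(sc$scale), c(1, sd(c(2, 4, 9))))
  expect_equal(colMeans(sc$scaled), c(a = 0, c = 0), tolerance = 1e-14)
  expect_equal(apply(sc$scaled, 2, sd), c(a = 1, c = 1), tolerance = 1e-14)
  # idempotence on already-standardized data
  sc2 <- autoscale(sc$scaled)
  expect_equal(sc2$scaled, sc$scaled, tolerance = 1e-12)

  Xna <- X; Xna[2, 3] <- NA
  expect_error(autoscale(Xna), "row 2, column c")
  expect_error(autoscale(X[1, , drop = FALSE]), "at least 2 rows")
})

test_that("two perfectly correlated columns put all variance on PC1", {
  X <- cbind(x = c(1, 2, 3, 4), y = 2 * c(1, 2, 3, 4) + 1)
  m <- fitChemSpace(X, 2, anchors = c(NA, NA))
  expect_equal(explainedVariance(m)[1], 1, tolerance = 1e-12)
  expect_equal(abs(unname(componentLoadings(m)[, 1])),
               c(1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("eigenvalues conserve total variance and match a brute-force oracle", {
  set.seed(7)
  for (rep_i in 1:5) {
    X <- matrix(rnorm(10 * 6), 10, 6,
                dimnames = list(NULL, paste0("d", 1:6)))
    m <- fitChemSpace(X, 3, anchors = c(NA, NA))
    lam <- eigenvalues(m)
    expect_equal(sum(lam), 6, tolerance = 1e-6 * 6)
    expect_true(all(diff(lam) <= 1e-12))
    oracle <- eigen(cov(scale(X)), symmetric = TRUE)$values
    expect_equal(lam, oracle, tolerance = 1e-10)
    expect_lte(sum(explainedVariance(m)), 1 + 1e-12)
  }
  expect_error(fitChemSpace(matrix(rnorm(20), 10, 2), 5), "exceeds")
})

test_that("projection reproduces training scores and centers the mean", {
  set.seed(11)
  X <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(paste0("r", 1:8),
                                                  paste0("d", 1:4)))
  m <- fitChemSpace(X, 2, anchors = c(NA, NA))
  pr <- projectScores(m, X)
  expect_equal(pr, trainingScores(m), tolerance = 1e-8, ignore_attr = TRUE)
  mu <- colMeans(X)
  expect_equal(unname(projectScores(m, mu)[1, ]), c(0, 0), tolerance = 1e-12)
  expect_error(projectScores(m, mu[-1]), "missing descriptor")
})

test_that("a hand-built two-descriptor projection equals the dot product", {
  X <- cbind(a = c(0, 1, 2, 3), b = c(3, 1, 2, 0))
  m <- fitChemSpace(X, 2, anchors = c(NA, NA))
  x_new <- c(a = 4, b = 1)
  z <- (x_new - m@center) / m@scale
  expect_equal(unname(projectScores(m, x_new)[1, ]),
               unname(drop(z %*% componentLoadings(m))), tolerance = 1e-12)
})

test_that("loading significance uses a strict threshold and the r identity", {
  set.seed(3)
  X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("d", 1:5)))
  m <- fitChemSpace(X, 2, anchors = c(NA, NA))
  rep_ <- interpretLoadings(m, X)
  # r equals a brute-force correlation oracle
  sc <- trainingScores(m)
  for (k in 1:2) {
    for (j in 1:5) {
      r_oracle <- cor(X[, j], sc[, k])
      got <- rep_$r[rep_$descriptor == paste0("d", j) &
                    rep_$component == paste0("PC", k)]
      expect_equal(got, r_oracle, tolerance = 1e-10)
    }
  }
  # r = loading * sqrt(lambda)
  lam <- eigenvalues(m)[1:2]
  L <- componentLoadings(m)
  rid <- sweep(L, 2, sqrt(lam), "*")
  expect_equal(matrix(rep_$r, ncol = 2), unname(rid), tolerance = 1e-8)
  # a threshold equal to an observed |r| is NOT flagged (strict >)
  r0 <- abs(rep_$r[3])
  rep2 <- interpretLoadings(m, X, threshold = r0)
  expect_false(rep2$significant[3])
  expect_identical(rep2$significant, abs(rep2$r) > r0)
})

test_that("a descriptor identical to the score is flagged with r = 1", {
  set.seed(5)
  base <- matrix(rnorm(20 * 3), 20, 3)
  m0 <- fitChemSpace(base, 1, anchors = NA)
  X <- cbind(base, mirror = drop(trainingScores(m0)))
  colnames(X) <- c("d1", "d2", "d3", "mirror")
  m <- fitChemSpace(X, 1, anchors = NA)
  rep_ <- interpretLoadings(m, X)
  r_mirror <- rep_$r[rep_$descriptor == "mirror"]
  expect_gt(abs(r_mirror), 0.99)
  expect_true(rep_$significant[rep_$descriptor == "mirror"])
})

test_that("full-rank reconstruction and score orthogonality hold", {
  set.seed(9)
  X <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(NULL, paste0("d", 1:4)))
  m <- fitChemSpace(X, 4, anchors = rep(NA, 4))
  Z <- scale(X)
  expect_equal(reconstructScaled(m), unname(Z), tolerance = 1e-8,
               ignore_attr = TRUE)
  sc <- trainingScores(m)
  cc <- cor(sc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
})

test_that("orientation anchors force size descriptors to load positively", {
  ref <- fixture_reference()
  desc <- descriptorTable(ref$ils)
  m <- fitChemSpace(desc)
  L <- componentLoadings(m)
  expect_gt(L["MW^C", 1], 0)
  expect_gt(L["MW^A", 2], 0)
})
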