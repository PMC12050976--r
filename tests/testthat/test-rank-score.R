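test_that("projection satisfies the weighted normal equations", {
  set.seed(20)
  n <- 300
  u <- runif(n, 0, 4)
  pos <- runif(n) > 0.3
  basis <- buildBasis(u[pos], nInterior = 2, order = 4)
  X <- cbind(rnorm(n), u^2, 1 + 0.5 * u)
  Xhat <- projectCovariates(X, u, basis, pos)
  B <- evalBasis(basis, u)
  orth <- crossprod(B[pos, ], Xhat[pos, ])
  expect_lt(max(abs(orth)), 1e-7)
})

test_that("projection annihilates columns in the spline span", {
  set.seed(21)
  n <- 250
  u <- runif(n, -1, 2)
  pos <- rep(TRUE, n)
  basis <- buildBasis(u, nInterior = 2, order = 4)
  spl <- drop(evalBasis(basis, u) %*% rnorm(basisDim(basis)))
  X <- cbind(spline_col = spl, const = rep(3, n), noise = rnorm(n))
  Xhat <- projectCovariates(X, u, basis, pos)
  expect_lt(max(abs(Xhat[, "spline_col"])), 1e-8)
  ## constants lie in the span by the partition of unity
  expect_lt(max(abs(Xhat[, "const"])), 1e-8)
  expect_gt(sd(Xhat[, "noise"]), 0.5)
})

test_that("score vanishes for a flat fitted link and follows the residual signs", {
  d <- makeDgpData(400, seed = 30)
  f <- suppressWarnings(fitNullQuantile(d, 0.5))
  fFlat <- f; fFlat@theta <- rep(1, length(f@theta))  # G constant
  expect_equal(empiricalScore(d, fFlat), 0, ignore_attr = TRUE,
               tolerance = 1e-12)
  ## all-positive residuals: score reduces to tau * mean(G' Zhat I(y>0))
  fLow <- f; fLow@theta <- f@theta - 1e6  # G far below all y
  ws <- ziqsir:::.scoreWorkspace(d, fLow)
  expect_equal(empiricalScore(d, fLow),
               drop(crossprod(ws$Zhat, 0.5 * ws$w)) / ws$n,
               tolerance = 1e-10)
})

test_that("adding a spline-of-index function to Z does not move the test", {
  d <- makeDgpData(500, seed = 31)
  f <- suppressWarnings(fitNullQuantile(d, 0.5))
  s1 <- empiricalScore(d, f)
  set.seed(8)
  u <- indexValues(f, adjustCovariates(d))
  spl <- drop(evalBasis(f@basis, u) %*% rnorm(length(f@theta)))
  Z2 <- testedCovariates(d) + spl
  d2 <- ziqData(response(d), Z2, adjustCovariates(d))
  s2 <- empiricalScore(d2, f)
  ## the projection removes the added component; with the internal
  ## standardisation the score changes only by the column scale ratio
  expect_equal(s2 * sd(Z2), s1 * sd(testedCovariates(d)),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## and the quadratic form is scale-free, hence exactly unmoved
  expect_equal(rankScoreTest(d2, f)@statistic,
               rankScoreTest(d, f)@statistic, tolerance = 1e-8)
})

test_that("covariance blocks agree with brute-force outer-product sums", {
  d <- makeDgpData(300, seed = 32)
  f <- suppressWarnings(fitNullQuantile(d, 0.25))
  om <- scoreCovariance(d, f)
  ws <- ziqsir:::.scoreWorkspace(d, f)
  ## brute force: n^{-1} sum_i g_i g_i', g_i = G'(u_i) Xhat_i I(y_i>0)
  Xhat <- cbind(ws$Zhat, ws$Chat)
  G <- matrix(0, ncol(Xhat), ncol(Xhat))
  for (i in seq_len(nrow(Xhat))) {
    g <- ws$w[i] * Xhat[i, ]
    G <- G + tcrossprod(g)
  }
  G <- G / ws$n
  p <- ncol(ws$Zhat)
  expect_equal(om$zz, G[1:p, 1:p, drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(om$zc, G[1:p, -(1:p), drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(om$cc, G[-(1:p), -(1:p), drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
  ## assembled matrix is symmetric PSD
  expect_equal(G, t(G), tolerance = 1e-12)
  expect_gt(min(eigen(G, symmetric = TRUE)$values), -1e-8)
})

test_that("statistic has the scalar closed form when p = 1, q = 0", {
  s <- 0.037; omegaZZ <- 0.21; n <- 400; tau <- 0.25
  omega <- list(zz = matrix(omegaZZ), zc = matrix(0, 1, 0),
                cz = matrix(0, 0, 1), cc = matrix(0, 0, 0))
  expect_equal(rankScoreStatistic(s, omega, n, tau),
               n * s^2 / (tau * (1 - tau) * omegaZZ), tolerance = 1e-12)
  expect_equal(rankScoreStatistic(0, omega, n, tau), 0)
  expect_error(rankScoreStatistic(numeric(0), omega, n, tau), "empty")
})

test_that("statistic is invariant to rescaling the tested covariates", {
  d <- makeDgpData(400, seed = 33)
  f <- suppressWarnings(fitNullQuantile(d, 0.5))
  t1 <- rankScoreTest(d, f)@statistic
  d2 <- ziqData(response(d), 7.3 * testedCovariates(d),
                adjustCovariates(d))
  t2 <- rankScoreTest(d2, f)@statistic
  expect_equal(t1, t2, tolerance = 1e-8)
})

test_that("statistic is invariant to affine recoding of the adjustment set", {
  d <- makeDgpData(500, seed = 34)
  f1 <- suppressWarnings(fitNullQuantile(d, 0.5, control = ziqControl(nStarts = 8L)))
  A <- matrix(c(2, 0.3, 0, 0, 0, 1.5, 0, 0, 0.2, 0, 1, 0, 0, 0, 0, 0.7),
              4, 4)
  C2 <- adjustCovariates(d) %*% A + rep(c(1, -2, 0, 3), each = 500)
  d2 <- ziqData(response(d), testedCovariates(d), C2)
  f2 <- suppressWarnings(fitNullQuantile(d2, 0.5, control = ziqControl(nStarts = 8L)))
  t1 <- rankScoreTest(d, f1)@statistic
  t2 <- rankScoreTest(d2, f2)@statistic
  ## loose: the optimum index is equivalent but knots shift slightly
  expect_lt(abs(t1 - t2), 0.5 + 0.2 * max(t1, t2))
})

test_that("chi-squared p-values invert the upper tail", {
  expect_equal(chisqPvalue(0, 1), 1)
  expect_equal(chisqPvalue(3.841459, 1), 0.05, tolerance = 1e-5)
  expect_true(all(diff(chisqPvalue(c(0.5, 1, 2, 4), 2)) < 0))
  expect_error(chisqPvalue(-1, 1), "negative")
})

test_that("permutation p-values hit their boundary cases and B is validated", {
  d <- makeDgpData(250, seed = 35)
  expect_error(ziqsirTest(d, mode = "permutation", B = 10, seed = 1),
               "at least 19")
  res <- suppressWarnings(ziqsirTest(d, mode = "permutation", B = 19, seed = 1))
  expect_gte(res@pValue, 1 / 20)
  expect_lte(res@pValue, 1)
})
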