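test_that("covariate distributions match their nominal moments", {
  X <- genCovariates(1e5, setting = 1, seed = 1)
  expect_equal(mean(X[, "x1"]), 0.5, tolerance = 0.01)
  ## three Monte Carlo standard errors
  expect_lt(abs(mean(X[, "x2"]) - 28), 3 * 2 / sqrt(1e5))
  expect_lt(abs(sd(X[, "x2"]) - 2), 0.02)
  expect_lt(abs(mean(X[, "x3"]) - 92.5), 3 * 13 / sqrt(1e5))
  expect_lt(abs(mean(X[, "x5"]) - 124), 3 * 18.5 / sqrt(1e5))
})

test_that("setting 2 couples (x2,x3) and (x4,x5) at their implied correlations", {
  X <- genCovariates(1e5, setting = 2, seed = 2)
  ## corr(x2, x3) = 2*4 / (2 * sqrt(4*4 + 81)) = 0.406...
  expect_equal(cor(X[, "x2"], X[, "x3"]), 8 / (2 * sqrt(97)),
               tolerance = 0.02)
  ## corr(x4, x5) = 1.3*144 / (12 * sqrt(1.69*144 + 7.75^2)) = 0.896...
  expect_equal(cor(X[, "x4"], X[, "x5"]),
               1.3 * 144 / (12 * sqrt(1.69 * 144 + 7.75^2)),
               tolerance = 0.01)
  ## means are unchanged relative to setting 1
  expect_lt(abs(mean(X[, "x3"]) - 92.5), 0.2)
  expect_lt(abs(mean(X[, "x5"]) - 124), 0.3)
})

test_that("generation is deterministic given a seed and restores the RNG", {
  set.seed(99); before <- runif(1); set.seed(99)
  X1 <- genCovariates(100, 1, seed = 7)
  X2 <- genCovariates(100, 1, seed = 7)
  expect_identical(X1, X2)
  expect_identical(runif(1), before)  # caller's stream untouched
  s1 <- simulateZiqData(200, 2, nullCoords = 2, seed = 13)
  s2 <- simulateZiqData(200, 2, nullCoords = 2, seed = 13)
  expect_identical(s1, s2)
})

test_that("presence probabilities are the expit of the linear predictor", {
  X <- genCovariates(50, 1, seed = 3)
  p0 <- presenceProbability(X, gamma = rep(0, 6))
  expect_equal(p0, rep(0.5, 50))
  p1 <- presenceProbability(X, gamma = c(-0.4, rep(0, 5)))
  expect_equal(p1, rep(plogis(-0.4), 50), tolerance = 1e-12)
  p <- presenceProbability(X)
  expect_true(all(p > 0 & p < 1))
})

test_that("quantile-coefficient curves evaluate as printed", {
  b <- dgpBeta(0.5)
  expect_equal(b[, "beta0"], -147.7 * 0.5 - 50 * 0.25 - 20,
               ignore_attr = TRUE)
  expect_equal(b[, "beta4"], 0.097 * sin(pi), ignore_attr = TRUE)
  b25 <- dgpBeta(0.25)
  expect_equal(b25[, "beta1"], 0.6 * 0.5 - 0.5, ignore_attr = TRUE)
  expect_error(dgpBeta(0), "\\(0, 1\\)")
})

test_that("the quartic link is zero at zero and increasing on u >= 0", {
  expect_equal(dgpLink(0.3, 0), 0)
  expect_equal(dgpLink(0.5, 10), 0.5 / 12 + 13.5 * 0.5 + 1.875 * 5)
  u <- seq(0, 50, length.out = 200)
  g <- dgpLink(0.7, u)
  expect_true(all(diff(g) > 0))
})

test_that("null coordinates remove the covariate effect from the response", {
  sim <- simulateZiqData(4000, 1, nullCoords = 1, seed = 21)
  ## x1 is binary: under its null the response distribution must not
  ## depend on it
  y0 <- sim$y[sim$X[, 1] == 0]
  y1 <- sim$y[sim$X[, 1] == 1]
  expect_gt(suppressWarnings(ks.test(y0, y1)$p.value), 0.01)
  ## and the zero rates must agree
  expect_lt(abs(mean(y0 == 0) - mean(y1 == 0)), 3 * 0.02)
})

test_that("conditional quantiles of generated data match the link", {
  ## freeze covariates, vary only tau: y must equal the quantile surface
  sim <- simulateZiqData(2e4, 1, seed = 31)
  pos <- sim$D == 1
  bet <- dgpBeta(sim$tau[pos])
  idx <- bet[, 1] + rowSums(sim$X[pos, ] * bet[, -1])
  expect_equal(sim$y[pos], pmax(dgpLink(sim$tau[pos], idx), 0),
               tolerance = 1e-12)
  ## empirical tau-quantile within a covariate bin tracks the DGP
  q75 <- dgpBeta(0.75)
  bin <- pos & abs(sim$X[, 2] - 28) < 1 & abs(sim$X[, 3] - 92.5) < 6 &
    abs(sim$X[, 4] - 80) < 6 & abs(sim$X[, 5] - 124) < 9 & sim$X[, 1] == 0
  expect_gt(sum(bin), 50)
  ref <- dgpLink(0.75, q75[1] + drop(colMeans(sim$X[bin, ]) %*% q75[-1]))
  expect_lt(abs(quantile(sim$y[bin], 0.75) / ref - 1), 0.25)
})
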