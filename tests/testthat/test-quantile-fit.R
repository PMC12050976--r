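test_that("check loss matches its piecewise-linear definition", {
  expect_equal(checkLoss(0, 0.3), 0)
  expect_equal(checkLoss(2, 0.25), 0.5)
  expect_equal(checkLoss(-2, 0.25), 1.5)
  u <- seq(-3, 3, by = 0.5)
  for (tau in c(0.1, 0.5, 0.9))
    expect_equal(checkLoss(u, tau),
                 ifelse(u > 0, tau * u, (tau - 1) * u))
  expect_error(checkLoss(1, 1.2), "\\(0, 1\\)")
})

test_that("single-span constant fit is the positive-part sample quantile", {
  set.seed(4)
  y <- c(rep(0, 30), rexp(170, 0.2))
  d <- ziqData(y, tested = rnorm(200), adjust = runif(200, 1, 2))
  b <- new("BSplineBasis", order = 1L, boundary = c(0.9, 2.1),
           interior = numeric(0))
  for (tau in c(0.25, 0.5, 0.75)) {
    th <- fitTheta(d, beta = 1, tau = tau, basis = b)
    ypos <- y[y > 0]
    ## minimiser of the check loss: compare achieved losses, since any
    ## point between adjacent order statistics can be optimal
    expect_lte(mean(checkLoss(ypos - th, tau)),
               mean(checkLoss(ypos - quantile(ypos, tau), tau)) + 1e-6)
    expect_lt(abs(mean(ypos < th) - tau), 0.05)
  }
})

test_that("data lying in the spline span are fitted with zero loss", {
  set.seed(5)
  n <- 150
  C <- matrix(runif(n, 0, 4))
  u <- drop(C)
  basis <- buildBasis(u, nInterior = 2, order = 4)
  theta0 <- c(2, 4, 3, 6, 5, 4)[seq_len(basisDim(basis))]
  y <- drop(evalBasis(basis, u) %*% theta0) + 5  # keep positive
  d <- ziqData(y, tested = rnorm(n), adjust = C)
  expect_lt(profileLoss(d, beta = 1, tau = 0.5,
                        control = ziqControl(nInterior = 2)), 1e-4)
})

test_that("profile loss is a minimum over spline coefficients", {
  set.seed(6)
  d <- makeCubicIndexData(200)
  beta <- c(0.6, 0.8)
  pl <- profileLoss(d, beta, tau = 0.5)
  pos <- response(d) > 0
  u <- drop(adjustCovariates(d) %*% beta)
  basis <- buildBasis(u[pos], order = 4)
  B <- evalBasis(basis, u[pos])
  n <- length(response(d))
  for (i in 1:100) {
    theta <- rnorm(basisDim(basis), sd = 3)
    lossAt <- sum(checkLoss(response(d)[pos] - drop(B %*% theta), 0.5)) / n
    expect_lte(pl, lossAt + 1e-8)
  }
})

test_that("rescaling the index direction leaves the profile loss invariant", {
  d <- makeCubicIndexData(300, seed = 8)
  l1 <- profileLoss(d, c(0.6, 0.8), tau = 0.5)
  l2 <- profileLoss(d, 2 * c(0.6, 0.8), tau = 0.5)
  expect_equal(l1, l2, tolerance = 1e-6)
})

test_that("solution is invariant to sample reordering", {
  d <- makeCubicIndexData(200, seed = 9)
  set.seed(1)
  perm <- sample(200)
  dP <- ziqData(response(d)[perm], testedCovariates(d)[perm, , drop = FALSE],
                adjustCovariates(d)[perm, , drop = FALSE])
  expect_equal(profileLoss(d, c(0.6, 0.8), 0.5),
               profileLoss(dP, c(0.6, 0.8), 0.5), tolerance = 1e-10)
})

test_that("one-dimensional adjustment fixes beta = +1 by the sign rule", {
  set.seed(10)
  n <- 200
  C <- matrix(runif(n, 1, 3))
  y <- pmax(drop(C)^2 + rnorm(n), 0)
  d <- ziqData(y, tested = rnorm(n), adjust = C)
  f <- fitNullQuantile(d, 0.5)
  expect_equal(f@beta, 1)
  expect_equal(sqrt(sum(f@beta^2)), 1, tolerance = 1e-8)
})

test_that("fit invariants hold: unit norm, sign, recorded loss", {
  d <- makeDgpData(400, seed = 3)
  f <- suppressWarnings(fitNullQuantile(d, 0.25))
  expect_equal(sqrt(sum(f@beta^2)), 1, tolerance = 1e-8)
  nz <- which(abs(f@beta) > 1e-12)
  expect_gt(f@beta[nz[1]], 0)
  ## recorded loss equals the objective at (beta, theta)
  pos <- positiveMask(d)
  u <- indexValues(f, adjustCovariates(d))
  resid <- response(d)[pos] - drop(evalBasis(f@basis, u[pos]) %*% f@theta)
  expect_equal(f@loss, sum(checkLoss(resid, 0.25)) / length(pos),
               tolerance = 1e-10)
})

test_that("null fit depends only on the response and adjustment columns", {
  d <- makeDgpData(400, seed = 4)
  ## replacing the tested covariates wholesale must leave the null fit
  ## bit-identical (they are held out of the restricted model)
  set.seed(77)
  d2 <- ziqData(response(d), tested = matrix(rcauchy(400)),
                adjust = adjustCovariates(d))
  set.seed(2); f1 <- suppressWarnings(fitNullQuantile(d, 0.5))
  set.seed(2); f2 <- suppressWarnings(fitNullQuantile(d2, 0.5))
  expect_identical(f1@beta, f2@beta)
  expect_identical(f1@theta, f2@theta)
})

test_that("index direction is recovered on cubic-link data", {
  ## median-level fit on y = (C'beta0)^3 + Phi^{-1}(tau_i), beta0 = (.6,.8)
  errs <- vapply(1:6, function(r) {
    d <- makeCubicIndexData(2000, seed = 100 + r)
    f <- suppressWarnings(fitNullQuantile(d, 0.5))
    sqrt(sum((f@beta - c(0.6, 0.8))^2))
  }, 0)
  expect_lt(mean(errs), 0.1)
})

test_that("identity-link data give a near-affine fitted link", {
  set.seed(15)
  n <- 2000
  C <- cbind(runif(n, 1, 3), runif(n, 0, 2))
  y <- pmax(drop(C %*% c(3, 4)) + rnorm(n), 0)
  d <- ziqData(y, tested = rnorm(n), adjust = C)
  f <- suppressWarnings(fitNullQuantile(d, 0.5))
  ## normalised direction close to (3,4)/5
  expect_lt(sqrt(sum((f@beta - c(0.6, 0.8))^2)), 0.1)
  u <- seq(f@basis@boundary[1], f@basis@boundary[2], length.out = 100)
  G <- predictG(f, u)$G
  expect_gt(summary(lm(G ~ u))$r.squared, 0.99)
})

test_that("predictG evaluates the spline and matches finite differences", {
  d <- makeCubicIndexData(500, seed = 16)
  f <- suppressWarnings(fitNullQuantile(d, 0.5))
  ## zero coefficients give the zero function
  f0 <- f; f0@theta <- rep(0, length(f@theta))
  pr <- predictG(f0, c(-0.5, 0, 0.5))
  expect_equal(pr$G, rep(0, 3))
  expect_equal(pr$G1, rep(0, 3))
  ## constant coefficients give a flat link (partition of unity)
  fc <- f; fc@theta <- rep(2.5, length(f@theta))
  prc <- predictG(fc, c(-0.2, 0.4))
  expect_equal(prc$G, rep(2.5, 2), tolerance = 1e-10)
  expect_equal(prc$G1, rep(0, 2), tolerance = 1e-8)
  ## derivative consistency at interior points
  rng <- f@basis@boundary
  u <- seq(rng[1] + 0.1 * diff(rng), rng[2] - 0.1 * diff(rng),
           length.out = 7)
  h <- 1e-6
  fd <- (predictG(f, u + h)$G - predictG(f, u - h)$G) / (2 * h)
  expect_equal(predictG(f, u)$G1, fd, tolerance = 1e-4)
})

test_that("the sphere search never does worse than its linear start", {
  for (s in c(2, 6)) {
    d <- makeDgpData(400, seed = s)
    pos <- positiveMask(d)
    C <- adjustCovariates(d)
    f <- suppressWarnings(fitNullQuantile(d, 0.5))
    ## linear quantile-regression direction as the reference start
    lin <- ziqsir:::.qrFit(cbind(1, scale(C)[pos, ]), response(d)[pos],
                           0.5)$coef[-1]
    lin <- lin / sqrt(sum(lin^2))
    linRaw <- lin / apply(C, 2, sd)
    ## small relative slack: the search phase evaluates the profile at a
    ## capped inner-iteration count, the recorded loss at the full cap
    expect_lte(f@loss, profileLoss(d, linRaw, 0.5) * (1 + 1e-3))
  }
})
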