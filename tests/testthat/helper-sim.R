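## Shared fixtures built in code.

## Small dataset with a smooth positive part: y|y>0 follows a cubic
## single-index in two positive covariates, so spline fits are easy.
makeCubicIndexData <- function(n, beta0 = c(0.6, 0.8), tau = NULL,
                               seed = 1) {
  set.seed(seed)
  C <- cbind(runif(n, 1, 2), runif(n, 1, 2))
  u <- drop(C %*% beta0)
  tv <- if (is.null(tau)) runif(n) else rep(tau, n)
  y <- pmax(u^3 + qnorm(tv), 0)
  Z <- matrix(rnorm(n), n, 1)
  ziqData(y, tested = Z, adjust = C)
}

## Quick default-ish dataset from the simulation DGP.
makeDgpData <- function(n = 400, setting = 1, nullCoords = 1, seed = 1,
                        test = nullCoords) {
  sim <- simulateZiqData(n, setting = setting, nullCoords = nullCoords,
                         seed = seed)
  simToZiqData(sim, test)
}

fastControl <- function(...) ziqControl(nStarts = 3L, ...)
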