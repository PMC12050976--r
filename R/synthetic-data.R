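## Run an expression with a temporarily seeded RNG, restoring the
## caller's stream afterwards; a NULL seed uses the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Default presence-model coefficients of the simulation DGP
#'
#' Intercept plus five slopes, chosen to mimic the presence pattern of a
#' moderately prevalent gut taxon (about one third of responses zero).
#'
#' @return numeric vector (gamma0, ..., gamma5).
#' @export
dgpGamma <- function() c(-0.4, -0.480, -0.022, 0.021, 0.015, -0.009)

#' Simulated covariates
#'
#' Five covariates emulating sex, BMI, waist circumference and the two
#' blood pressures: `x1 ~ Bernoulli(0.5)`, `x2 ~ N(28, 2^2)`,
#' `x4 ~ N(80, 12^2)`; under Setting 1 additionally independent
#' `x3 ~ N(92.5, 13^2)` and `x5 ~ N(124, 18.5^2)`, while Setting 2
#' couples `x3 = 2 x2 + N(36.5, 9^2)` and `x5 = 1.3 x4 + N(20, 7.75^2)`
#' (correlations about 0.41 and 0.90).
#'
#' @param n sample size.
#' @param setting 1 (independent) or 2 (correlated).
#' @param seed optional seed; the caller's RNG stream is restored.
#' @return n x 5 matrix with columns `x1..x5`.
#' @export
genCovariates <- function(n, setting = 1, seed = NULL) {
  stopifnot(n >= 1)
  if (!setting %in% c(1, 2)) stop("'setting' must be 1 or 2")
  withSeed(seed, {
    x1 <- stats::rbinom(n, 1, 0.5)
    x2 <- stats::rnorm(n, 28, 2)
    if (setting == 1) {
      x3 <- stats::rnorm(n, 92.5, 13)
      x4 <- stats::rnorm(n, 80, 12)
      x5 <- stats::rnorm(n, 124, 18.5)
    } else {
      x3 <- 2 * x2 + stats::rnorm(n, 36.5, 9)
      x4 <- stats::rnorm(n, 80, 12)
      x5 <- 1.3 * x4 + stats::rnorm(n, 20, 7.75)
    }
    cbind(x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5)
  })
}

#' Presence probability of the simulation DGP
#'
#' Expit of the linear predictor \eqn{\gamma_0 + \sum_j \gamma_j x_j}.
#'
#' @param X covariate matrix (n x 5).
#' @param gamma coefficient vector (intercept first, length ncol(X)+1).
#' @return vector of probabilities strictly in (0, 1).
#' @export
presenceProbability <- function(X, gamma = dgpGamma()) {
  X <- as.matrix(X)
  stopifnot(length(gamma) == ncol(X) + 1L)
  stats::plogis(gamma[1] + drop(X %*% gamma[-1]))
}

#' Quantile-coefficient curves of the simulation DGP
#'
#' The six coefficient functions of the positive-part quantile process:
#' \deqn{\beta_0(\tau) = -147.7\tau - 50\tau^2 - 20,\quad
#'   \beta_1(\tau) = 0.6\sqrt{\tau} - 2\tau,\quad
#'   \beta_2(\tau) = 2.2\tau^2,}
#' \deqn{\beta_3(\tau) = \tau^2/30 + 0.02,\quad
#'   \beta_4(\tau) = 0.097\sin(2\pi\tau),\quad
#'   \beta_5(\tau) = 0.086(-3\tau^2 + \tau).}
#'
#' @param tau quantile level(s) in (0, 1).
#' @return matrix `length(tau)` x 6 with columns `beta0..beta5`.
#' @export
dgpBeta <- function(tau) {
  if (any(tau <= 0) || any(tau >= 1)) stop("'tau' must lie in (0, 1)")
  cbind(beta0 = -147.7 * tau - 50 * tau^2 - 20,
        beta1 = 0.6 * sqrt(tau) - 2 * tau,
        beta2 = 2.2 * tau^2,
        beta3 = tau^2 / 30 + 0.02,
        beta4 = 0.097 * sin(2 * pi * tau),
        beta5 = 0.086 * (-3 * tau^2 + tau))
}

#' Quantile link of the simulation DGP
#'
#' \eqn{G_\tau(u) = \frac{1}{12}\tau(0.1u)^4 + 13.5\tau(0.1u)^2 +
#' 1.875\tau u}, a quartic strictly increasing in \eqn{u} on
#' \eqn{u \ge 0} for \eqn{\tau > 0}.
#'
#' @param tau quantile level(s) in (0, 1).
#' @param u index value(s).
#' @return numeric vector of link values.
#' @export
dgpLink <- function(tau, u) {
  if (any(tau <= 0) || any(tau >= 1)) stop("'tau' must lie in (0, 1)")
  (1 / 12) * tau * (0.1 * u)^4 + 13.5 * tau * (0.1 * u)^2 + 1.875 * tau * u
}

#' Simulate one zero-inflated dataset
#'
#' Draws covariates for the chosen setting, a presence indicator
#' \eqn{D_i} from the logistic model with coefficients `gamma`, and a
#' nominal level \eqn{\tau_i \sim U(0,1)}; positive responses are set to
#' the conditional quantile
#' \eqn{Y_i = G_{\tau_i}(\beta_0(\tau_i) + X_i^\top \beta(\tau_i))} and
#' zeros wherever \eqn{D_i = 0}.  Coordinates listed in `nullCoords`
#' have both their presence coefficient \eqn{\gamma_j} and quantile
#' curve \eqn{\beta_j(\cdot)} zeroed, giving the null data-generating
#' process for those covariates.  A negative link value (possible only
#' in extreme tails of the index) is clamped to zero and counted in
#' `clamped`.
#'
#' @param n sample size.
#' @param setting 1 or 2, see [genCovariates()].
#' @param nullCoords integer subset of 1..5 whose effects are zeroed.
#' @param gamma presence-model coefficients (intercept first).
#' @param seed optional seed; the caller's RNG stream is restored.
#' @param roundCounts round positive responses to integer counts
#'   (off by default).
#' @return list with elements `X` (n x 5), `y`, `tau`, `D`, `prob`,
#'   `clamped` (count of clamped draws), `setting`, `nullCoords`.
#' @examples
#' sim <- simulateZiqData(500, setting = 1, nullCoords = 1, seed = 1)
#' mean(sim$y == 0)
#' @export
simulateZiqData <- function(n, setting = 1, nullCoords = integer(0),
                            gamma = dgpGamma(), seed = NULL,
                            roundCounts = FALSE) {
  stopifnot(all(nullCoords %in% 1:5))
  withSeed(seed, {
    X <- genCovariates(n, setting)
    g <- gamma
    if (length(nullCoords)) g[nullCoords + 1L] <- 0
    prob <- presenceProbability(X, g)
    D <- stats::rbinom(n, 1, prob)
    tau <- stats::runif(n)
    bet <- dgpBeta(tau)
    if (length(nullCoords)) bet[, nullCoords + 1L] <- 0
    index <- bet[, 1] + rowSums(X * bet[, -1, drop = FALSE])
    yPos <- dgpLink(tau, index)
    clamped <- sum(D == 1 & yPos < 0)
    y <- ifelse(D == 1, pmax(yPos, 0), 0)
    if (roundCounts) y <- round(y)
    list(X = X, y = y, tau = tau, D = D, prob = prob,
         clamped = clamped, setting = setting,
         nullCoords = as.integer(nullCoords))
  })
}

#' Split a simulated dataset into tested and adjustment covariates
#'
#' @param sim result of [simulateZiqData()].
#' @param testCoords integer coordinates (1..5) to test; the remaining
#'   columns become adjustment covariates.
#' @return A [ZiqData-class] object.
#' @export
simToZiqData <- function(sim, testCoords) {
  stopifnot(all(testCoords %in% seq_len(ncol(sim$X))))
  ziqData(sim$y, tested = sim$X[, testCoords, drop = FALSE],
          adjust = sim$X[, -testCoords, drop = FALSE])
}
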