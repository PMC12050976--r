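#' Centre-heavy weights for a grid of quantile levels
#'
#' \eqn{w_s \propto \tau_s I(\tau_s \le 0.5) + (1-\tau_s) I(\tau_s >
#' 0.5)}, normalised to sum to one: central levels get the largest
#' weight, the tails the smallest.
#'
#' @param levels strictly increasing quantile levels in (0, 1).
#' @return weight vector summing to one.
#' @examples
#' quantileWeights(c(0.1, 0.25, 0.5, 0.75, 0.9))
#' # 1/12  5/24  5/12  5/24  1/12
#' @export
quantileWeights <- function(levels) {
  if (any(levels <= 0) || any(levels >= 1))
    stop("quantile levels must lie strictly inside (0, 1)")
  if (is.unsorted(levels, strictly = TRUE))
    stop("quantile levels must be strictly increasing")
  raw <- ifelse(levels <= 0.5, levels, 1 - levels)
  raw / sum(raw)
}

#' Observed zero proportion
#'
#' @param y non-negative response vector.
#' @return \eqn{\hat r_n = \#\{y_i = 0\}/n}.
#' @export
zeroProportion <- function(y) {
  if (!length(y)) stop("empty response")
  if (any(y < 0)) stop("response must be non-negative")
  mean(y == 0)
}

## Clip p-values away from 0/1 so tan{(0.5 - p) * pi} stays finite.
.clipP <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

#' Weighted Cauchy combination of the two-part p-values
#'
#' \eqn{T_C = \hat r_n \tan\{(0.5 - p^L)\pi\} + (1 - \hat r_n) \sum_s
#' w_s \tan\{(0.5 - p^Q_{\tau_s})\pi\}}; under the global null
#' \eqn{T_C} is approximately standard Cauchy, so the combined p-value
#' is its upper-tail probability \eqn{0.5 - \arctan(T_C)/\pi}.
#' Component p-values are clipped to \eqn{[10^{-15}, 1-10^{-15}]} so an
#' underflowed component cannot produce an infinite statistic.
#'
#' @param pLogistic presence-model p-value.
#' @param pQuantile vector of per-level quantile p-values.
#' @param rHat observed zero proportion in \[0, 1\].
#' @param weights quantile-level weights summing to one; defaults to
#'   [quantileWeights()] applied to the names of `pQuantile`, or equal
#'   weights when no levels are available.
#' @return A [ZiqCombined-class] object.
#' @export
cauchyCombine <- function(pLogistic, pQuantile, rHat, weights = NULL) {
  stopifnot(rHat >= 0, rHat <= 1)
  if (is.null(weights)) {
    lv <- suppressWarnings(as.numeric(names(pQuantile)))
    weights <- if (length(lv) && !anyNA(lv)) quantileWeights(lv)
               else rep(1 / length(pQuantile), length(pQuantile))
  }
  stopifnot(length(weights) == length(pQuantile))
  pl <- .clipP(pLogistic)
  pq <- .clipP(pQuantile)
  stat <- rHat * tan((0.5 - pl) * pi) +
    (1 - rHat) * sum(weights * tan((0.5 - pq) * pi))
  new("ZiqCombined", pLogistic = as.numeric(pLogistic),
      pQuantile = as.numeric(pQuantile), rHat = rHat,
      weights = as.numeric(weights), statistic = stat,
      pValue = stats::pcauchy(stat, lower.tail = FALSE))
}

#' @describeIn ZiqCombined-class compact display
#' @param object a `ZiqCombined`
#' @export
setMethod("show", "ZiqCombined", function(object) {
  cat(sprintf(
    "ZiqCombined: T_C = %.4g, p = %.4g (r_hat = %.3f, p_L = %.4g, %d quantile level(s))\n",
    object@statistic, object@pValue, object@rHat, object@pLogistic,
    length(object@pQuantile)))
  invisible(object)
})
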