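#' @import methods
NULL

#' Normalised B-spline basis on a clamped knot vector
#'
#' Represents an order-\eqn{m} normalised B-spline basis on \eqn{[a, b]}
#' with \eqn{N_n} strictly increasing interior knots.  The basis dimension
#' is \eqn{J_n = N_n + m}.  The boundary knots carry multiplicity \eqn{m}
#' (clamped ends), so basis values at any point in \eqn{[a, b]} are
#' non-negative and sum to one.
#'
#' @slot order integer spline order \eqn{m \ge 1} (4 = cubic).
#' @slot boundary numeric length-2, the interval end points \eqn{a < b}.
#' @slot interior numeric vector of strictly increasing interior knots in
#'   \eqn{(a, b)}; may be empty.
#'
#' @seealso [buildBasis()], [evalBasis()], [evalBasisDeriv()]
#' @export
setClass("BSplineBasis",
  representation(order = "integer", boundary = "numeric",
                 interior = "numeric"))

setValidity("BSplineBasis", function(object) {
  msg <- character()
  if (length(object@order) != 1L || object@order < 1L)
    msg <- c(msg, "'order' must be a single integer >= 1")
  if (length(object@boundary) != 2L || !all(is.finite(object@boundary)) ||
      object@boundary[1] >= object@boundary[2])
    msg <- c(msg, "'boundary' must be two finite values a < b")
  if (length(object@interior)) {
    if (is.unsorted(object@interior, strictly = TRUE))
      msg <- c(msg, "interior knots must be strictly increasing")
    if (any(object@interior <= object@boundary[1]) ||
        any(object@interior >= object@boundary[2]))
      msg <- c(msg, "interior knots must lie strictly inside (a, b)")
  }
  if (length(msg)) msg else TRUE
})

#' Zero-inflated outcome with tested and adjustment covariates
#'
#' Container for one testing problem: a non-negative response `y`, the
#' tested covariates `Z` (n x p) whose association with `y` is under the
#' null hypothesis, and the adjustment covariates `C` (n x q) that enter
#' the presence model and the single index of the positive-part quantile
#' model.  The positive mask \eqn{D_i = I(y_i > 0)} is derived, not stored.
#' No intercept column should be supplied: the logistic model adds its own
#' and the single-index link absorbs location shifts.
#'
#' @slot response numeric non-negative vector of length n.
#' @slot tested numeric matrix n x p.
#' @slot adjust numeric matrix n x q.
#'
#' @seealso [ziqData()], [ziqsirTest()]
#' @export
setClass("ZiqData",
  representation(response = "numeric", tested = "matrix",
                 adjust = "matrix"))

setValidity("ZiqData", function(object) {
  msg <- character()
  n <- length(object@response)
  if (any(!is.finite(object@response)) || any(object@response < 0))
    msg <- c(msg, "'response' must be finite and non-negative")
  if (nrow(object@tested) != n)
    msg <- c(msg, "nrow(tested) must equal length(response)")
  if (nrow(object@adjust) != n)
    msg <- c(msg, "nrow(adjust) must equal length(response)")
  if (ncol(object@tested) < 1L)
    msg <- c(msg, "at least one tested covariate is required")
  if (any(!is.finite(object@tested)) || any(!is.finite(object@adjust)))
    msg <- c(msg, "covariates must be finite")
  if (length(msg)) msg else TRUE
})

#' Null single-index quantile fit for the positive part
#'
#' The restricted (null) estimate at quantile level `tau`: the unit-norm
#' index direction `beta` over the adjustment covariates, and the B-spline
#' coefficients `theta` representing the link \eqn{\hat G_\tau}.  Fitting
#' is performed on internally standardised covariates; `center` and
#' `scale` record that transformation and `betaStd` the direction on the
#' standardised scale (the `basis` lives on the standardised index).
#' `beta` is reported on the raw covariate scale, unit-norm, with the
#' first coordinate of largest absolute size-free sign fixed so that the
#' first nonzero coordinate is positive.
#'
#' @slot tau quantile level in (0, 1).
#' @slot beta unit-norm direction on the raw covariate scale.
#' @slot betaStd unit-norm direction on the standardised scale.
#' @slot center,scale standardisation constants for the adjustment columns.
#' @slot theta spline coefficients of the fitted link.
#' @slot basis the [BSplineBasis-class] on the standardised index.
#' @slot loss achieved profile check loss (mean over all n samples).
#' @slot converged logical optimiser status flag.
#' @slot nPositive number of strictly positive responses used.
#'
#' @seealso [fitNullQuantile()], [predictG()]
#' @export
setClass("NullQuantileFit",
  representation(tau = "numeric", beta = "numeric", betaStd = "numeric",
                 center = "numeric", scale = "numeric", theta = "numeric",
                 basis = "BSplineBasis", loss = "numeric",
                 converged = "logical", nPositive = "integer"))

#' Per-quantile rank-score test result
#'
#' The empirical rank score for the tested covariates at one quantile
#' level, the blocks of the estimated score covariance
#' \eqn{\hat\Omega_\tau} (partitioned into tested `zz` and adjustment
#' `cc` coordinates), the quadratic-form statistic and its asymptotic
#' chi-squared p-value.
#'
#' @slot tau quantile level.
#' @slot score empirical score, length p.
#' @slot omega list with elements `zz` (p x p), `zc` (p x q), `cz`
#'   (q x p), `cc` (q x q).
#' @slot statistic non-negative rank-score statistic.
#' @slot df degrees of freedom (p).
#' @slot pValue upper-tail chi-squared p-value.
#'
#' @seealso [rankScoreTest()]
#' @export
setClass("ScoreResult",
  representation(tau = "numeric", score = "numeric", omega = "list",
                 statistic = "numeric", df = "integer", pValue = "numeric"))

#' Logistic presence/absence model fit
#'
#' Maximum-likelihood logistic regression of the presence indicator
#' \eqn{D = I(Y > 0)} on a design matrix (intercept added internally).
#' Under (quasi-)separation the coefficients are capped at +/- 15 and the
#' fit is flagged rather than failing, so batch runs proceed.
#'
#' @slot coefficients named coefficient vector (intercept first).
#' @slot logLik maximised log-likelihood (at the capped coefficients when
#'   separation was detected).
#' @slot converged logical IRLS status.
#' @slot separated logical separation flag.
#'
#' @seealso [fitLogistic()], [logisticLrtPvalue()]
#' @export
setClass("LogisticFit",
  representation(coefficients = "numeric", logLik = "numeric",
                 converged = "logical", separated = "logical"))

#' Cauchy-combined test result
#'
#' Weighted Cauchy combination of the logistic likelihood-ratio p-value
#' and the per-quantile rank-score p-values.  The zero proportion
#' \eqn{\hat r_n} weights the presence part; the quantile levels get
#' centre-heavy weights summing to one.
#'
#' @slot pLogistic presence-model p-value.
#' @slot pQuantile per-level quantile p-values (named by level).
#' @slot rHat observed zero proportion.
#' @slot weights quantile-level weights.
#' @slot statistic the combined Cauchy statistic.
#' @slot pValue standard-Cauchy upper-tail p-value of `statistic`.
#'
#' @seealso [cauchyCombine()]
#' @export
setClass("ZiqCombined",
  representation(pLogistic = "numeric", pQuantile = "numeric",
                 rHat = "numeric", weights = "numeric",
                 statistic = "numeric", pValue = "numeric"))

#' Full ZIQ-SIR test result
#'
#' Result of the complete two-part test: the logistic likelihood-ratio
#' p-value, per-quantile rank-score results, and the Cauchy-combined
#' p-value.  In permutation mode the reported p-values are permutation
#' tail fractions (the asymptotic ones are kept in `perTau`).
#'
#' @slot pValue final combined p-value.
#' @slot combined the [ZiqCombined-class] built from asymptotic
#'   component p-values.
#' @slot perTau data.frame with one row per quantile level: `tau`,
#'   `statistic`, `df`, `pAsymptotic`, and `pPermutation` when available.
#' @slot pLogistic logistic LRT p-value (asymptotic).
#' @slot mode `"asymptotic"` or `"permutation"`.
#' @slot nPermutations number of permutations used (0 in asymptotic mode).
#' @slot rHat observed zero proportion.
#' @slot pTcPermutation tail fraction of the permuted combined Cauchy
#'   statistic (a secondary readout; `NA` in asymptotic mode).
#' @slot fits list of [NullQuantileFit-class] objects (empty unless
#'   requested).
#'
#' @seealso [ziqsirTest()]
#' @export
setClass("ZiqTest",
  representation(pValue = "numeric", combined = "ZiqCombined",
                 perTau = "data.frame", pLogistic = "numeric",
                 mode = "character", nPermutations = "integer",
                 rHat = "numeric", pTcPermutation = "numeric",
                 fits = "list"))
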