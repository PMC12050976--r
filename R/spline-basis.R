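#' Build a normalised B-spline basis from index values
#'
#' Places boundary knots at the range of `indexValues` and `nInterior`
#' interior knots at equally spaced empirical quantiles, giving a basis of
#' dimension `nInterior + order`.  Quantile placement (rather than equal
#' spacing in value) keeps knot spans populated when the index
#' distribution is skewed.  Tied quantiles are collapsed, so the realised
#' dimension can be smaller for heavily discrete indices.
#'
#' @param indexValues numeric vector of index values the basis should
#'   cover; needs at least `order + 1` distinct values.
#' @param nInterior number of interior knots \eqn{N_n \ge 0}.  The
#'   default applies the slow-growth rule
#'   \eqn{\max(1, \mathrm{round}(n^{1/5}))} with `n = length(indexValues)`.
#' @param order spline order \eqn{m} (4 = cubic, the default).
#' @return A [BSplineBasis-class] object.
#' @examples
#' b <- buildBasis(0:10, nInterior = 0, order = 4)
#' basisDim(b)  # 4
#' @export
buildBasis <- function(indexValues, nInterior = NULL, order = 4L) {
  order <- as.integer(order)
  stopifnot(order >= 1L)
  u <- indexValues[is.finite(indexValues)]
  if (length(unique(u)) < order + 1L)
    stop("degenerate basis: need at least order + 1 distinct index values")
  if (is.null(nInterior))
    nInterior <- max(1L, as.integer(round(length(u)^(1 / 5))))
  nInterior <- as.integer(nInterior)
  stopifnot(nInterior >= 0L)
  a <- min(u); b <- max(u)
  interior <- if (nInterior > 0L) {
    kn <- stats::quantile(u, probs = seq_len(nInterior) / (nInterior + 1),
                          names = FALSE, type = 7)
    unique(kn[kn > a & kn < b])
  } else numeric(0)
  new("BSplineBasis", order = order, boundary = c(a, b),
      interior = as.numeric(interior))
}

#' Dimension of a B-spline basis
#'
#' @param basis a [BSplineBasis-class].
#' @return \eqn{J_n = N_n + m}, the number of basis functions.
#' @export
basisDim <- function(basis) {
  stopifnot(is(basis, "BSplineBasis"))
  length(basis@interior) + basis@order
}

## Full knot vector with clamped (multiplicity-m) boundary knots.
fullKnots <- function(basis) {
  c(rep(basis@boundary[1], basis@order), basis@interior,
    rep(basis@boundary[2], basis@order))
}

clampToRange <- function(u, basis) {
  pmin(pmax(u, basis@boundary[1]), basis@boundary[2])
}

#' Evaluate a normalised B-spline basis
#'
#' Rows are non-negative and sum to one (partition of unity).  Points
#' outside the knot range are clamped to the nearest boundary before
#' evaluation, so iterative refits never extrapolate.
#'
#' @param basis a [BSplineBasis-class].
#' @param u numeric vector of evaluation points.
#' @return matrix `length(u)` x `basisDim(basis)`.
#' @export
evalBasis <- function(basis, u) {
  stopifnot(is(basis, "BSplineBasis"))
  x <- clampToRange(u, basis)
  splines::splineDesign(fullKnots(basis), x, ord = basis@order)
}

#' Evaluate first derivatives of a B-spline basis
#'
#' Rows sum to zero (derivative of the partition of unity).  Evaluation
#' points are clamped as in [evalBasis()].
#'
#' @inheritParams evalBasis
#' @return matrix `length(u)` x `basisDim(basis)` of first derivatives.
#' @export
evalBasisDeriv <- function(basis, u) {
  stopifnot(is(basis, "BSplineBasis"))
  if (basis@order < 2L)
    stop("derivative undefined for order-1 (piecewise constant) basis")
  x <- clampToRange(u, basis)
  splines::splineDesign(fullKnots(basis), x, ord = basis@order,
                        derivs = rep(1L, length(x)))
}

#' @describeIn BSplineBasis-class compact display
#' @param object a `BSplineBasis`
#' @export
setMethod("show", "BSplineBasis", function(object) {
  cat(sprintf(
    "BSplineBasis: order %d on [%.4g, %.4g], %d interior knot(s), dimension %d\n",
    object@order, object@boundary[1], object@boundary[2],
    length(object@interior), basisDim(object)))
  invisible(object)
})
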