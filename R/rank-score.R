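## Moore-Penrose pseudo-inverse; singular values below tol * max are dropped.
pinvMat <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  if (any(dim(A) == 0L)) return(t(A))
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Center columns; scale by sd (or 1 for constant columns).
.standardize <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  sweep(sweep(X, 2, ctr), 2, scl, "/")
}

#' Project covariates onto the spline span of the index
#'
#' Computes \eqn{\hat X_i = X_i - \hat E(X_i \mid u_i)}, where the
#' conditional expectation is the weighted least-squares projection onto
#' the B-spline basis evaluated at the index, with weights
#' \eqn{I(Y_i > 0)}: only the strictly positive observations enter the
#' Gram matrix, but residuals are returned for every row.  Singular Gram
#' matrices are handled by a pseudo-inverse.
#'
#' @param X numeric matrix n x k.
#' @param index numeric index values, length n.
#' @param basis a [BSplineBasis-class] covering the index.
#' @param positiveMask logical length-n inclusion mask.
#' @return matrix n x k of projection residuals; over the masked rows the
#'   columns are orthogonal to the basis columns.
#' @export
projectCovariates <- function(X, index, basis, positiveMask) {
  X <- as.matrix(X)
  stopifnot(length(index) == nrow(X), length(positiveMask) == nrow(X))
  if (sum(positiveMask) < basisDim(basis))
    stop("fewer positive observations than basis dimension")
  Ball <- evalBasis(basis, index)
  Bpos <- Ball[positiveMask, , drop = FALSE]
  M <- pinvMat(crossprod(Bpos)) %*%
    crossprod(Bpos, X[positiveMask, , drop = FALSE])
  X - Ball %*% M
}

## Shared pieces of the score computation for one fitted level.  All
## score/covariance sums run over positive rows only (the I(Y>0) factor),
## so everything is restricted to them; covariates are standardised for
## conditioning (the statistic is invariant to affine recodings).
.scoreWorkspace <- function(data, fit) {
  pos <- positiveMask(data)
  n <- length(pos)
  u <- indexValues(fit, data@adjust)
  Zs <- .standardize(data@tested)
  Cs <- .standardize(data@adjust)
  Ball <- evalBasis(fit@basis, u)
  Bpos <- Ball[pos, , drop = FALSE]
  pinvGram <- pinvMat(crossprod(Bpos))
  proj <- function(V) {
    V - Bpos %*% (pinvGram %*% crossprod(Bpos, V))
  }
  upos <- u[pos]
  g <- predictG(fit, upos)
  w <- g$G1
  a <- fit@tau - (data@response[pos] - g$G < 0)
  Chat <- proj(Cs[pos, , drop = FALSE])
  list(n = n, pos = pos, tau = fit@tau, Zs = Zs, Bpos = Bpos,
       pinvGram = pinvGram, proj = proj, w = w, a = a,
       Zhat = proj(Zs[pos, , drop = FALSE]), Chat = Chat,
       Wc = Chat * w, omegaCC = crossprod(Chat * w) / n)
}

#' Empirical rank score for the tested covariates
#'
#' \eqn{\hat s = n^{-1} \sum_i \{\tau - I(Y_i - \hat G_\tau(u_i) < 0)\}
#' \hat G^{(1)}_\tau(u_i) \hat Z_i I(Y_i > 0)} with \eqn{\hat Z_i} the
#' projection residual of the tested covariates given the fitted index.
#'
#' @param data a [ZiqData-class].
#' @param fit a [NullQuantileFit-class] for the same data.
#' @return numeric score vector of length p.
#' @export
empiricalScore <- function(data, fit) {
  ws <- .scoreWorkspace(data, fit)
  drop(crossprod(ws$Zhat, ws$a * ws$w)) / ws$n
}

#' Score covariance blocks
#'
#' \eqn{\hat\Omega_\tau = n^{-1}\sum_i \hat g_i \hat g_i^\top} with
#' \eqn{\hat g_i = \hat G^{(1)}_\tau(u_i)\, \hat X_i\, I(Y_i>0)},
#' partitioned into tested (`zz`) and adjustment (`cc`) coordinates.
#'
#' @inheritParams empiricalScore
#' @return list of blocks `zz` (p x p), `zc` (p x q), `cz` (q x p),
#'   `cc` (q x q).
#' @export
scoreCovariance <- function(data, fit) {
  ws <- .scoreWorkspace(data, fit)
  Wz <- ws$Zhat * ws$w
  list(zz = crossprod(Wz) / ws$n, zc = crossprod(Wz, ws$Wc) / ws$n,
       cz = crossprod(ws$Wc, Wz) / ws$n, cc = ws$omegaCC)
}

#' Rank-score quadratic-form statistic
#'
#' \eqn{T_\tau = n\{\tau(1-\tau)\}^{-1} \hat s^\top S^+ \hat s} where
#' \eqn{S = \Omega_{zz} - \Omega_{zc}\Omega_{cc}^+\Omega_{cz}} is the
#' Schur complement projecting out the adjustment (nuisance) block, so
#' the quadratic form always has the dimension of the tested covariates.
#'
#' @param score empirical score vector (length p >= 1).
#' @param omega list of blocks as returned by [scoreCovariance()]; the
#'   `cc` block may be 0 x 0 when there are no adjustment covariates.
#' @param n total sample size.
#' @param tau quantile level.
#' @return non-negative scalar statistic.
#' @export
rankScoreStatistic <- function(score, omega, n, tau) {
  p <- length(score)
  if (p == 0L) stop("empty score: nothing to test")
  S <- omega$zz
  if (!is.null(omega$cc) && length(omega$cc))
    S <- S - omega$zc %*% pinvMat(omega$cc) %*% omega$cz
  stat <- n / (tau * (1 - tau)) *
    drop(crossprod(score, pinvMat(S) %*% score))
  max(stat, 0)
}

#' Upper-tail chi-squared p-value
#'
#' @param statistic non-negative test statistic.
#' @param df degrees of freedom.
#' @return p-value in \[0, 1\], monotone decreasing in `statistic`.
#' @export
chisqPvalue <- function(statistic, df) {
  if (any(statistic < 0)) stop("negative statistic")
  stopifnot(df >= 1)
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Rank-score test at one quantile level
#'
#' Assembles the empirical score, its covariance blocks, the Schur
#' complement quadratic form and the asymptotic chi-squared p-value with
#' p degrees of freedom.
#'
#' @inheritParams empiricalScore
#' @return A [ScoreResult-class] object.
#' @export
rankScoreTest <- function(data, fit) {
  ws <- .scoreWorkspace(data, fit)
  s <- drop(crossprod(ws$Zhat, ws$a * ws$w)) / ws$n
  Wz <- ws$Zhat * ws$w
  omega <- list(zz = crossprod(Wz) / ws$n, zc = crossprod(Wz, ws$Wc) / ws$n,
                cz = crossprod(ws$Wc, Wz) / ws$n, cc = ws$omegaCC)
  stat <- rankScoreStatistic(s, omega, ws$n, fit@tau)
  p <- length(s)
  new("ScoreResult", tau = fit@tau, score = s, omega = omega,
      statistic = stat, df = as.integer(p),
      pValue = chisqPvalue(stat, p))
}

#' @describeIn ScoreResult-class compact display
#' @param object a `ScoreResult`
#' @export
setMethod("show", "ScoreResult", function(object) {
  cat(sprintf("ScoreResult: tau = %.3g, T = %.4g on %d df, p = %.4g\n",
              object@tau, object@statistic, object@df, object@pValue))
  invisible(object)
})
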