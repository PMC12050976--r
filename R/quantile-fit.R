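#' Tuning parameters for the single-index quantile fit
#'
#' @param order B-spline order (4 = cubic).
#' @param nInterior interior knot count; `NULL` applies
#'   \eqn{\max(1, \mathrm{round}(n_+^{1/5}))} where \eqn{n_+} is the
#'   number of positive responses.
#' @param minPositive minimum number of positive responses required to
#'   attempt a fit.
#' @param nStarts number of optimiser starts for the index direction:
#'   the normalised linear quantile-regression coefficient vector plus
#'   random unit vectors (plus a warm start when supplied).
#' @param nmMaxit,nmReltol iteration cap and relative tolerance of the
#'   derivative-free simplex search over sphere angles.
#' @param irlsMaxit,irlsMaxitFinal,irlsTol,irlsEps iteration caps
#'   (search phase / final refit), relative loss tolerance and residual
#'   smoothing floor of the inner iteratively-reweighted quantile
#'   regression.
#' @param permThreshold positive-sample count at or above which the
#'   asymptotic chi-squared calibration is used instead of permutation.
#' @param permResidual permute residuals of the tested covariates on
#'   the adjustment covariates (Freedman-Lane style) instead of raw
#'   rows; keeps the permutation null valid when tested and adjustment
#'   covariates are correlated.  On by default.
#' @param capCoef absolute cap applied to logistic coefficients under
#'   separation.
#' @return A named list of control values.
#' @export
ziqControl <- function(order = 4L, nInterior = NULL, minPositive = 30L,
                       nStarts = 5L, nmMaxit = 200L, nmReltol = 1e-4,
                       irlsMaxit = 30L, irlsMaxitFinal = 300L,
                       irlsTol = 1e-8, irlsEps = 1e-6,
                       permThreshold = 1000L, permResidual = TRUE,
                       capCoef = 15) {
  list(order = as.integer(order), nInterior = nInterior,
       minPositive = as.integer(minPositive), nStarts = as.integer(nStarts),
       nmMaxit = as.integer(nmMaxit), nmReltol = nmReltol,
       irlsMaxit = as.integer(irlsMaxit),
       irlsMaxitFinal = as.integer(irlsMaxitFinal),
       irlsTol = irlsTol, irlsEps = irlsEps,
       permThreshold = as.integer(permThreshold),
       permResidual = isTRUE(permResidual), capCoef = capCoef)
}

#' Quantile check loss
#'
#' \eqn{\rho_\tau(u) = u\{\tau - I(u < 0)\}}, the piecewise-linear loss
#' with slope \eqn{\tau} for positive and \eqn{\tau - 1} for negative
#' arguments.
#'
#' @param u numeric vector of residuals.
#' @param tau quantile level in (0, 1).
#' @return non-negative vector of losses.
#' @examples
#' checkLoss(c(-2, 0, 2), 0.25)  # 1.5, 0, 0.5
#' @export
checkLoss <- function(u, tau) {
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0 || tau >= 1)
    stop("'tau' must be a single value in (0, 1)")
  u * (tau - (u < 0))
}

## Linear-in-parameters quantile regression via smoothed IRLS (compiled).
.qrFit <- function(X, y, tau, maxit = 100L, tol = 1e-8, eps = 1e-6) {
  fit <- .irls_qr(as.matrix(X), as.numeric(y), tau, maxit, tol, eps)
  fit$coef <- drop(fit$coef)
  fit
}

#' Spline coefficients minimising the positive-part check loss
#'
#' Given an index direction, evaluates the basis at the index of the
#' strictly positive observations and solves the linear-in-parameters
#' quantile regression of the response on the basis columns.
#'
#' @param data a [ZiqData-class].
#' @param beta index coefficients for the adjustment covariates (raw
#'   scale).
#' @param tau quantile level.
#' @param basis a [BSplineBasis-class] built on the current index; if
#'   `NULL`, one is built from the positive-row index values.
#' @param alpha optional coefficients for the tested covariates (zero
#'   under the null, the default).
#' @param control see [ziqControl()].
#' @return numeric vector of spline coefficients (length `basisDim`).
#' @export
fitTheta <- function(data, beta, tau, basis = NULL, alpha = NULL,
                     control = ziqControl()) {
  stopifnot(is(data, "ZiqData"))
  pos <- positiveMask(data)
  u <- drop(data@adjust %*% beta)
  if (!is.null(alpha)) u <- u + drop(data@tested %*% alpha)
  if (is.null(basis))
    basis <- buildBasis(u[pos], nInterior = .nInteriorRule(sum(pos), control),
                        order = control$order)
  if (sum(pos) < basisDim(basis))
    stop("underdetermined fit: fewer positive observations than basis dimension")
  B <- evalBasis(basis, u[pos])
  .qrFit(B, data@response[pos], tau, control$irlsMaxitFinal,
         control$irlsTol, control$irlsEps)$coef
}

.nInteriorRule <- function(nPos, control) {
  if (!is.null(control$nInterior)) as.integer(control$nInterior)
  else max(1L, as.integer(round(nPos^(1 / 5))))
}

#' Profile check loss of an index direction
#'
#' The pseudo-likelihood minimised over the spline coefficients, with
#' the basis rebuilt from the index values of the current direction.
#' Reported on the scale of the full objective: the sum of check losses
#' over positive observations divided by the total sample size n.
#'
#' @inheritParams fitTheta
#' @param final use the tighter final-refit iteration cap.
#' @return non-negative scalar loss.
#' @export
profileLoss <- function(data, beta, tau, alpha = NULL,
                        control = ziqControl(), final = TRUE) {
  pos <- positiveMask(data)
  u <- drop(data@adjust %*% beta)
  if (!is.null(alpha)) u <- u + drop(data@tested %*% alpha)
  .profileLossIndex(u[pos], data@response[pos], tau, length(pos),
                    control, final = final)
}

## Core profile evaluation on an already-restricted positive-row index.
## Mirrors buildBasis()/evalBasis() but skips object construction: this
## sits inside the optimiser loop.
.profileLossIndex <- function(upos, ypos, tau, nTotal, control, final = FALSE) {
  ord <- control$order
  a <- min(upos); b <- max(upos)
  nInt <- .nInteriorRule(length(upos), control)
  interior <- if (nInt > 0L) {
    kn <- stats::quantile(upos, probs = seq_len(nInt) / (nInt + 1),
                          names = FALSE, type = 7)
    unique(kn[kn > a & kn < b])
  } else numeric(0)
  B <- splines::splineDesign(c(rep(a, ord), interior, rep(b, ord)), upos,
                             ord = ord)
  maxit <- if (final) control$irlsMaxitFinal else control$irlsMaxit
  fit <- .irls_qr(B, ypos, tau, maxit, control$irlsTol, control$irlsEps)
  fit$loss * length(ypos) / nTotal
}

## Spherical parametrisation of the unit sphere: q-1 angles <-> unit q-vector.
sphToVec <- function(phi) {
  q <- length(phi) + 1L
  v <- numeric(q); s <- 1
  for (j in seq_len(q - 1L)) {
    v[j] <- s * cos(phi[j])
    s <- s * sin(phi[j])
  }
  v[q] <- s
  v
}

vecToSph <- function(v) {
  v <- v / sqrt(sum(v^2))
  q <- length(v)
  phi <- numeric(q - 1L); s <- 1
  for (j in seq_len(q - 1L)) {
    phi[j] <- acos(min(max(v[j] / s, -1), 1))
    s2 <- s * sin(phi[j])
    s <- if (abs(s2) < 1e-12) 1e-12 else s2
  }
  phi
}

#' Fit the null single-index quantile model
#'
#' Estimates the unit-norm index direction over the adjustment
#' covariates and the B-spline link coefficients at level `tau`,
#' minimising the profile check loss with the tested covariates held out
#' (their coefficients fixed at zero).  Covariates are standardised
#' internally; knots track the index distribution, being rebuilt from
#' the current index at every profile evaluation.  The nonsmooth profile
#' loss is minimised over sphere angles by multi-start Nelder-Mead (a
#' grid-plus-golden-section search when only two adjustment covariates
#' are present, where the sphere is a circle).
#'
#' @param data a [ZiqData-class]; needs at least one adjustment column.
#' @param tau quantile level in (0, 1).
#' @param control see [ziqControl()].
#' @param warmStart optional unit vector on the *standardised* covariate
#'   scale used as an additional optimiser start (typically `betaStd` of
#'   a fit at a neighbouring level).
#' @return A [NullQuantileFit-class] object.  Non-convergence of the
#'   simplex search is reported via the `converged` flag and a warning,
#'   not an error.
#' @export
fitNullQuantile <- function(data, tau, control = ziqControl(),
                            warmStart = NULL) {
  stopifnot(is(data, "ZiqData"))
  if (length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("'tau' must be a single value in (0, 1)")
  q <- ncol(data@adjust)
  if (q < 1L) stop("at least one adjustment covariate is required")
  pos <- positiveMask(data)
  nPos <- sum(pos)
  n <- length(pos)
  if (nPos < control$minPositive)
    stop(sprintf("only %d positive responses (minimum %d)", nPos,
                 control$minPositive))
  center <- colMeans(data@adjust)
  scl <- apply(data@adjust, 2, stats::sd)
  Cs <- sweep(sweep(data@adjust, 2, center), 2, scl, "/")
  Cpos <- Cs[pos, , drop = FALSE]
  ypos <- data@response[pos]
  nInt <- .nInteriorRule(nPos, control)
  if (nPos < nInt + control$order)
    stop("underdetermined fit: fewer positive observations than basis dimension")

  obj <- function(b) .profileLossIndex(drop(Cpos %*% b), ypos, tau, n, control)

  converged <- TRUE
  if (q == 1L) {
    betaStd <- 1
  } else {
    ## linear quantile-regression start
    lin <- .qrFit(cbind(1, Cpos), ypos, tau, control$irlsMaxitFinal,
                  control$irlsTol, control$irlsEps)$coef[-1]
    nl <- sqrt(sum(lin^2))
    starts <- list(if (nl > 1e-10) lin / nl else NULL,
                   if (!is.null(warmStart)) warmStart / sqrt(sum(warmStart^2)))
    starts <- Filter(Negate(is.null), starts)
    nRandom <- max(0L, control$nStarts - length(starts))
    for (k in seq_len(nRandom)) {
      r <- stats::rnorm(q)
      starts[[length(starts) + 1L]] <- r / sqrt(sum(r^2))
    }
    if (q == 2L) {
      ## circle: coarse angular grid refined by golden-section search
      phis <- sort(unique(c(seq(0, 2 * pi, length.out = 25L)[-25L],
                            vapply(starts, function(s) atan2(s[2], s[1]),
                                   0))))
      vals <- vapply(phis, function(p) obj(c(cos(p), sin(p))), 0)
      p0 <- phis[which.min(vals)]
      opt <- stats::optimize(function(p) obj(c(cos(p), sin(p))),
                             interval = p0 + c(-0.3, 0.3), tol = 1e-5)
      betaStd <- c(cos(opt$minimum), sin(opt$minimum))
      if (opt$objective > min(vals) + 1e-12)
        betaStd <- c(cos(p0), sin(p0))
    } else {
      ## early-stopped multistart: further starts are only spent while
      ## the best two runs disagree (guards against local minima of the
      ## nonsmooth profile loss without paying for five searches when
      ## the first two already agree)
      best <- NULL; second <- Inf
      for (s in starts) {
        o <- stats::optim(vecToSph(s), function(phi) obj(sphToVec(phi)),
                          method = "Nelder-Mead",
                          control = list(maxit = control$nmMaxit,
                                         reltol = control$nmReltol))
        if (is.null(best) || o$value < best$value) {
          second <- if (is.null(best)) Inf else best$value
          best <- o
        } else second <- min(second, o$value)
        if (is.finite(second) &&
            (second - best$value) < 1e-3 * (abs(best$value) + 1e-12))
          break
      }
      betaStd <- sphToVec(best$par)
      converged <- best$convergence == 0L
      if (!converged)
        warning(sprintf(
          "index search did not fully converge at tau = %.3g; best iterate returned",
          tau))
    }
  }

  ## sign convention on the raw-scale direction: first nonzero coordinate > 0
  betaRaw <- betaStd / scl
  betaRaw <- betaRaw / sqrt(sum(betaRaw^2))
  nz <- which(abs(betaRaw) > 1e-12)
  if (length(nz) && betaRaw[nz[1]] < 0) {
    betaRaw <- -betaRaw
    betaStd <- -betaStd
  }

  upos <- drop(Cpos %*% betaStd)
  basis <- buildBasis(upos, nInterior = nInt, order = control$order)
  B <- evalBasis(basis, upos)
  fin <- .qrFit(B, ypos, tau, control$irlsMaxitFinal, control$irlsTol,
                control$irlsEps)
  new("NullQuantileFit", tau = tau, beta = as.numeric(betaRaw),
      betaStd = as.numeric(betaStd), center = as.numeric(center),
      scale = as.numeric(scl), theta = as.numeric(fin$coef), basis = basis,
      loss = fin$loss * nPos / n, converged = converged,
      nPositive = as.integer(nPos))
}

#' Standardised index values of a null fit
#'
#' @param fit a [NullQuantileFit-class].
#' @param C adjustment covariate matrix on the raw scale (defaults to
#'   the columns the fit was built from are not stored, so it must be
#'   supplied).
#' @return numeric vector of standardised index values
#'   \eqn{C_i^\top \hat\beta} on the scale of the fit's basis.
#' @export
indexValues <- function(fit, C) {
  stopifnot(is(fit, "NullQuantileFit"))
  C <- as.matrix(C)
  Cs <- sweep(sweep(C, 2, fit@center), 2, fit@scale, "/")
  drop(Cs %*% fit@betaStd)
}

#' Evaluate the fitted link and its derivative
#'
#' \eqn{\hat G_\tau(u) = B(u)^\top \tilde\theta} and
#' \eqn{\hat G^{(1)}_\tau(u) = B^{(1)}(u)^\top \tilde\theta} at points on
#' the fit's (standardised) index scale.
#'
#' @param fit a [NullQuantileFit-class].
#' @param u numeric vector of index values.
#' @return list with components `G` and `G1`.
#' @export
predictG <- function(fit, u) {
  stopifnot(is(fit, "NullQuantileFit"))
  list(G = drop(evalBasis(fit@basis, u) %*% fit@theta),
       G1 = drop(evalBasisDeriv(fit@basis, u) %*% fit@theta))
}

#' @describeIn NullQuantileFit-class compact display
#' @param object a `NullQuantileFit`
#' @export
setMethod("show", "NullQuantileFit", function(object) {
  cat(sprintf(
    "NullQuantileFit: tau = %.3g, q = %d, n+ = %d, loss = %.6g%s\n",
    object@tau, length(object@beta), object@nPositive, object@loss,
    if (object@converged) "" else " (not converged)"))
  cat("  beta:", paste(sprintf("%.4f", object@beta), collapse = " "), "\n")
  invisible(object)
})
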