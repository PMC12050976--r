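#' Full two-part association test for a zero-inflated outcome
#'
#' Runs the complete procedure: (i) logistic likelihood-ratio test of
#' the tested covariates in the presence/absence model; (ii) a
#' single-index quantile rank-score test at each level of `taus` for the
#' positive part; (iii) a weighted Cauchy combination of the component
#' p-values, with the zero proportion weighting the presence part.
#'
#' With `mode = "auto"`, asymptotic chi-squared calibration is used when
#' the number of positive responses reaches `control$permThreshold` and a
#' permutation scheme otherwise.  The permutation scheme exploits that
#' the null fit depends only on `(y, C)`: it is computed once, and each
#' permutation re-draws the rows of `Z` jointly (preserving within-`Z`
#' dependence; by default the residuals of `Z` on `C` are permuted so
#' that `Z`-`C` correlation is preserved too), recomputing only the
#' projection, score, covariance, statistic and logistic test.
#' Per-level permutation p-values are
#' \eqn{(1 + \#\{T_b \ge T_{obs}\})/(B + 1)}; the reported combined
#' p-value Cauchy-combines these permutation-calibrated level p-values
#' with the logistic LRT p-value.  The tail fraction of the permuted
#' combined statistic is kept in `pTcPermutation` as a secondary
#' readout.
#'
#' @param y non-negative response vector, or a [ZiqData-class] (in which
#'   case `tested`/`adjust` are ignored).
#' @param tested covariates under test (vector or n x p matrix).
#' @param adjust adjustment covariates (vector or n x q matrix, no
#'   intercept column).
#' @param taus quantile grid; default the common 5-level grid.
#' @param mode `"auto"`, `"asymptotic"` or `"permutation"`.
#' @param B number of permutations (>= 19) in permutation mode.
#' @param seed optional integer seed covering optimiser starts and
#'   permutations.
#' @param control see [ziqControl()].
#' @param keepFits keep the per-level [NullQuantileFit-class] objects.
#' @return A [ZiqTest-class] object.
#' @examples
#' sim <- simulateZiqData(300, setting = 1, seed = 7)
#' d <- simToZiqData(sim, testCoords = 1)
#' \donttest{ziqsirTest(d, B = 99, seed = 1)}
#' @export
ziqsirTest <- function(y, tested = NULL, adjust = NULL,
                       taus = c(0.1, 0.25, 0.5, 0.75, 0.9),
                       mode = c("auto", "asymptotic", "permutation"),
                       B = 199L, seed = NULL, control = ziqControl(),
                       keepFits = FALSE) {
  mode <- match.arg(mode)
  data <- if (is(y, "ZiqData")) y else ziqData(y, tested, adjust)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(data@response)
  nPos <- nPositive(data)
  if (mode == "auto")
    mode <- if (nPos >= control$permThreshold) "asymptotic" else "permutation"
  if (mode == "permutation" && B < 19L)
    stop("B must be at least 19 for usable permutation resolution")

  d <- as.numeric(positiveMask(data))
  Zs <- .standardize(data@tested)
  Cs <- .standardize(data@adjust)
  p <- ncol(Zs)
  full <- .logisticCore(d, cbind(Zs, Cs), cap = control$capCoef)
  red <- .logisticCore(d, Cs, cap = control$capCoef)
  pLog <- chisqPvalue(max(2 * (full$logLik - red$logLik), 0), p)

  ## null fits: central level first, neighbours warm-started from it
  ord <- order(abs(taus - 0.5))
  fits <- vector("list", length(taus))
  warm <- NULL
  for (k in ord) {
    fits[[k]] <- fitNullQuantile(data, taus[k], control = control,
                                 warmStart = warm)
    if (is.null(warm)) warm <- fits[[k]]@betaStd
  }
  scores <- lapply(fits, function(f) rankScoreTest(data, f))
  statObs <- vapply(scores, function(s) s@statistic, 0)
  pAsym <- vapply(scores, function(s) s@pValue, 0)
  names(pAsym) <- taus
  rHat <- zeroProportion(data@response)
  wts <- quantileWeights(taus)
  combAsym <- cauchyCombine(pLog, pAsym, rHat, wts)

  perTau <- data.frame(tau = taus, statistic = statObs,
                       df = rep(p, length(taus)), pAsymptotic = pAsym,
                       row.names = NULL)
  if (mode == "asymptotic") {
    res <- new("ZiqTest", pValue = combAsym@pValue, combined = combAsym,
               perTau = perTau, pLogistic = pLog, mode = mode,
               nPermutations = 0L, rHat = rHat,
               pTcPermutation = NA_real_,
               fits = if (keepFits) fits else list())
    return(res)
  }

  perm <- .permutationEngine(data, fits, Zs, Cs, d, red$logLik, B,
                             rHat, wts, control)
  perTau$pPermutation <-
    vapply(seq_along(taus), function(k)
      (1 + sum(perm$statTau[, k] >= statObs[k])) / (B + 1), 0)
  ## primary small-sample p-value: each quantile level calibrated by its
  ## own permutation tail, then Cauchy-combined with the (classically
  ## calibrated) logistic LRT p-value.  Inside the combination the
  ## mid-p version (#{>=} + 0.5)/(B + 1) is used: on the discrete
  ## permutation support the plain tail fraction has a negative-biased
  ## tan transform (a p of exactly 1 maps to a huge negative term),
  ## making the combined test conservative; the mid-p support is
  ## symmetric around 1/2, so the transform is unbiased under the null
  pMid <- vapply(seq_along(taus), function(k)
    (0.5 + sum(perm$statTau[, k] >= statObs[k])) / (B + 1), 0)
  combPerm <- cauchyCombine(pLog, stats::setNames(pMid, taus),
                            rHat, wts)
  ## tail fraction of the permuted combined statistic, kept as a
  ## secondary readout
  pTc <- (1 + sum(perm$statC >= combAsym@statistic)) / (B + 1)
  new("ZiqTest", pValue = combPerm@pValue, combined = combPerm,
      perTau = perTau, pLogistic = pLog, mode = mode,
      nPermutations = as.integer(B), rHat = rHat,
      pTcPermutation = pTc, fits = if (keepFits) fits else list())
}

## Permutation engine: the null fits are fixed; only the Z-dependent
## pieces (projection residuals, score, covariance blocks, logistic LRT)
## are recomputed for each joint row permutation of Z.
.permutationEngine <- function(data, fits, Zs, Cs, d, llReduced, B,
                               rHat, wts, control) {
  n <- nrow(Zs)
  p <- ncol(Zs)
  pos <- positiveMask(data)
  ws <- lapply(fits, function(f) .scoreWorkspace(data, f))
  ccInv <- lapply(ws, function(w) pinvMat(w$omegaCC))
  statTau <- matrix(NA_real_, B, length(fits))
  statC <- numeric(B)
  ## Freedman-Lane style residual permutation: permuting raw Z rows
  ## would destroy any Z-C dependence and invalidate the null when the
  ## tested covariates are correlated with adjustment covariates (the
  ## coupled-covariate setting), so the linear fit of Z on C is kept
  ## fixed and only its residuals are re-drawn
  if (ncol(Cs) && isTRUE(control$permResidual)) {
    Cd <- cbind(1, Cs)
    cf <- qr.coef(qr(Cd), Zs)
    cf[is.na(cf)] <- 0
    Fhat <- Cd %*% cf
    Rz <- Zs - Fhat
  } else {
    Fhat <- matrix(0, n, p)
    Rz <- Zs
  }
  for (b in seq_len(B)) {
    idx <- sample.int(n)
    Zp <- Fhat + Rz[idx, , drop = FALSE]
    Zpos <- Zp[pos, , drop = FALSE]
    pTauB <- numeric(length(fits))
    for (k in seq_along(fits)) {
      w <- ws[[k]]
      Zhat <- w$proj(Zpos)
      s <- drop(crossprod(Zhat, w$a * w$w)) / n
      Wz <- Zhat * w$w
      omega <- list(zz = crossprod(Wz) / n,
                    zc = crossprod(Wz, w$Wc) / n,
                    cz = crossprod(w$Wc, Wz) / n, cc = w$omegaCC)
      S <- omega$zz - omega$zc %*% ccInv[[k]] %*% omega$cz
      stat <- max(n / (w$tau * (1 - w$tau)) *
                    drop(crossprod(s, pinvMat(S) %*% s)), 0)
      statTau[b, k] <- stat
      pTauB[k] <- chisqPvalue(stat, p)
    }
    fullB <- .logisticCore(d, cbind(Zp, Cs), cap = control$capCoef)
    pLogB <- chisqPvalue(max(2 * (fullB$logLik - llReduced), 0), p)
    statC[b] <- rHat * tan((0.5 - .clipP(pLogB)) * pi) +
      (1 - rHat) * sum(wts * tan((0.5 - .clipP(pTauB)) * pi))
  }
  list(statTau = statTau, statC = statC)
}

#' @describeIn ZiqTest-class compact display
#' @param object a `ZiqTest`
#' @export
setMethod("show", "ZiqTest", function(object) {
  cat(sprintf("ZIQ-SIR test (%s mode%s)\n", object@mode,
              if (object@nPermutations > 0)
                sprintf(", B = %d", object@nPermutations) else ""))
  cat(sprintf("  zero proportion: %.3f\n", object@rHat))
  cat(sprintf("  presence (logistic LRT) p = %.4g\n", object@pLogistic))
  pt <- object@perTau
  for (i in seq_len(nrow(pt)))
    cat(sprintf("  tau = %-5.3g T = %8.4g  p = %.4g\n",
                pt$tau[i], pt$statistic[i],
                if (!is.null(pt$pPermutation)) pt$pPermutation[i]
                else pt$pAsymptotic[i]))
  cat(sprintf("  combined p-value: %.4g\n", object@pValue))
  invisible(object)
})

#' @describeIn ZiqTest-class combined p-value accessor
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @describeIn ZiqTest-class combined p-value accessor
#' @export
setMethod("pValue", "ZiqTest", function(object) object@pValue)

#' @describeIn ZiqTest-class per-level results accessor
#' @export
setGeneric("perTauResults", function(object) standardGeneric("perTauResults"))

#' @describeIn ZiqTest-class per-level results accessor
#' @export
setMethod("perTauResults", "ZiqTest", function(object) object@perTau)
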