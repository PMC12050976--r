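## Core logistic fit on a design matrix WITHOUT intercept column added.
## Returns coefficients (intercept first), log-likelihood, flags.
.logisticCore <- function(d, X, cap = 15) {
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- .newton_logistic(Xd, as.numeric(d), cap = cap)
  cf <- drop(fit$coef)
  names(cf) <- colnames(Xd)
  list(coef = cf, logLik = fit$logLik, converged = fit$converged,
       separated = fit$separated)
}

#' Logistic regression for presence/absence
#'
#' Maximum-likelihood logistic fit of the presence indicator on a design
#' matrix (an intercept is added internally).  Perfect or quasi
#' separation is flagged and the coefficients are capped at
#' `control$capCoef` in absolute value instead of failing, so per-feature
#' batch runs are never aborted; the reported log-likelihood is evaluated
#' at the capped coefficients.
#'
#' @param d logical or 0/1 vector: presence indicator.
#' @param X numeric design matrix (no intercept column); may have zero
#'   columns for an intercept-only fit.
#' @param control see [ziqControl()] (only `capCoef` is used).
#' @return A [LogisticFit-class] object.
#' @examples
#' f <- fitLogistic(c(0, 1, 0, 1), matrix(numeric(0), 4, 0))
#' coef(f)  # intercept = logit(0.5) = 0
#' @export
fitLogistic <- function(d, X = matrix(numeric(0), length(d), 0),
                        control = ziqControl()) {
  d <- as.numeric(d)
  if (length(unique(d)) < 2L)
    stop("presence indicator has a single class")
  X <- as.matrix(X)
  core <- .logisticCore(d, X, cap = control$capCoef)
  if (core$separated)
    warning("separation detected in logistic fit; coefficients capped")
  new("LogisticFit", coefficients = core$coef, logLik = core$logLik,
      converged = core$converged, separated = core$separated)
}

#' @describeIn fitLogistic coefficient accessor
#' @param object a [LogisticFit-class]
#' @param ... unused
#' @export
setMethod("coef", "LogisticFit", function(object, ...) object@coefficients)

#' @describeIn fitLogistic log-likelihood accessor
#' @export
setMethod("logLik", "LogisticFit", function(object, ...) object@logLik)

#' Likelihood-ratio test between nested logistic fits
#'
#' The statistic \eqn{2(\ell_{full} - \ell_{reduced})} is floored at
#' zero and referred to the chi-squared distribution.
#'
#' @param full,reduced [LogisticFit-class] objects, `reduced` nested in
#'   `full`.
#' @param df degrees of freedom; defaults to the difference in parameter
#'   count.
#' @return upper-tail chi-squared p-value.
#' @export
logisticLrtPvalue <- function(full, reduced, df = NULL) {
  stopifnot(is(full, "LogisticFit"), is(reduced, "LogisticFit"))
  if (is.null(df))
    df <- length(full@coefficients) - length(reduced@coefficients)
  if (df < 1L) stop("'full' must have more parameters than 'reduced'")
  stat <- 2 * (full@logLik - reduced@logLik)
  if (stat < -1e-6)
    stop("models do not appear nested: reduced fit has higher likelihood")
  chisqPvalue(max(stat, 0), df)
}

#' @describeIn LogisticFit-class compact display
#' @param object a `LogisticFit`
#' @export
setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit: %d coefficient(s), logLik = %.4g%s\n",
              length(object@coefficients), object@logLik,
              if (object@separated) " (separation: capped)" else ""))
  invisible(object)
})
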