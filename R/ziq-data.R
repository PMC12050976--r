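#' Construct a ZiqData object
#'
#' Bundles a non-negative response with the tested covariate matrix `Z`
#' and the adjustment covariate matrix `C`.  Vectors are promoted to
#' one-column matrices.  Constant columns must not be supplied: the
#' logistic part adds its own intercept and the single-index link absorbs
#' location, so an intercept inside the index is not identifiable.
#'
#' @param y non-negative numeric response of length n.
#' @param tested numeric matrix (or vector) of covariates under test.
#' @param adjust numeric matrix (or vector) of adjustment covariates.
#' @return A [ZiqData-class] object.
#' @examples
#' d <- ziqData(c(0, 1.5, 2, 0, 3), tested = rnorm(5), adjust = rnorm(5))
#' nPositive(d)
#' @export
ziqData <- function(y, tested, adjust) {
  tested <- as.matrix(tested)
  adjust <- as.matrix(adjust)
  storage.mode(tested) <- "double"
  storage.mode(adjust) <- "double"
  if (is.null(colnames(tested)))
    colnames(tested) <- paste0("z", seq_len(ncol(tested)))
  if (ncol(adjust) && is.null(colnames(adjust)))
    colnames(adjust) <- paste0("c", seq_len(ncol(adjust)))
  constC <- ncol(adjust) > 0 && any(apply(adjust, 2, stats::sd) == 0)
  if (constC)
    stop("constant adjustment column supplied; remove the intercept from 'adjust'")
  new("ZiqData", response = as.numeric(y), tested = tested, adjust = adjust)
}

#' @rdname ziqData
#' @param object,x a [ZiqData-class]
#' @export
setGeneric("positiveMask", function(object) standardGeneric("positiveMask"))

#' @rdname ziqData
#' @export
setMethod("positiveMask", "ZiqData", function(object) object@response > 0)

#' @rdname ziqData
#' @export
setGeneric("nPositive", function(object) standardGeneric("nPositive"))

#' @rdname ziqData
#' @export
setMethod("nPositive", "ZiqData", function(object) sum(object@response > 0))

#' @rdname ziqData
#' @export
setGeneric("response", function(object) standardGeneric("response"))

#' @rdname ziqData
#' @export
setMethod("response", "ZiqData", function(object) object@response)

#' @rdname ziqData
#' @export
setGeneric("testedCovariates", function(object) standardGeneric("testedCovariates"))

#' @rdname ziqData
#' @export
setMethod("testedCovariates", "ZiqData", function(object) object@tested)

#' @rdname ziqData
#' @export
setGeneric("adjustCovariates", function(object) standardGeneric("adjustCovariates"))

#' @rdname ziqData
#' @export
setMethod("adjustCovariates", "ZiqData", function(object) object@adjust)

#' @describeIn ziqData compact display
#' @export
setMethod("show", "ZiqData", function(object) {
  n <- length(object@response)
  cat(sprintf(
    "ZiqData: n = %d (%d positive, %.1f%% zero), p = %d tested, q = %d adjustment\n",
    n, nPositive(object), 100 * mean(object@response == 0),
    ncol(object@tested), ncol(object@adjust)))
  invisible(object)
})
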