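#' Filter features by zero proportion
#'
#' Keeps features (rows) whose observed zero proportion is strictly
#' below `maxZeroProp`; features dominated by zeros give unreliable
#' positive-part fits.
#'
#' @param counts non-negative matrix, features x samples.
#' @param maxZeroProp threshold in (0, 1\]; default 0.8.
#' @return the filtered matrix (possibly with zero rows, with a
#'   warning).
#' @export
filterFeatures <- function(counts, maxZeroProp = 0.8) {
  counts <- as.matrix(counts)
  stopifnot(maxZeroProp > 0, maxZeroProp <= 1)
  zp <- rowMeans(counts == 0)
  keep <- zp < maxZeroProp
  if (!any(keep)) warning("no features pass the zero-proportion filter")
  counts[keep, , drop = FALSE]
}

#' Jitter positive counts
#'
#' Adds U(0, 1) noise to strictly positive entries so continuous-outcome
#' quantile methods apply; zeros are left untouched, preserving the
#' zero pattern exactly.
#'
#' @param counts non-negative vector or matrix.
#' @param seed optional seed; the caller's RNG stream is restored.
#' @return numeric object of the same shape.
#' @export
jitterCounts <- function(counts, seed = NULL) {
  withSeed(seed, {
    pos <- counts > 0
    counts[pos] <- counts[pos] + stats::runif(sum(pos))
    counts
  })
}

#' Per-sample library sizes
#'
#' Column sums of a (filtered) feature table, used as an adjustment
#' covariate to absorb sequencing-depth differences.
#'
#' @param counts non-negative matrix, features x samples.
#' @return numeric vector, one total per sample; all-zero samples give
#'   0 with a warning.
#' @export
librarySizeCovariate <- function(counts) {
  ls <- colSums(as.matrix(counts))
  if (any(ls == 0)) warning("sample(s) with zero library size")
  ls
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA`s are passed through.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return monotone q-values capped at 1.
#' @export
bhAdjust <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

## Dummy-code a covariate data.frame: factors/characters expand to
## treatment contrasts with lexicographically first level as reference.
.dummyCode <- function(df) {
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v, levels = sort(unique(as.character(v))))
      if (nlevels(f) < 2L)
        stop(sprintf("covariate '%s' has a single level", nm))
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1])
      m
    } else matrix(as.numeric(v), ncol = 1,
                  dimnames = list(NULL, nm))
  })
  do.call(cbind, cols)
}

#' Test every feature of a count table
#'
#' Applies the full two-part test to each row of a feature table:
#' positive counts are jittered (per feature, seeded), the per-sample
#' library size of the supplied table is appended to the adjustment
#' covariates (unless disabled), categorical covariates are
#' dummy-coded with lexicographic reference levels, and samples with
#' missing covariates are dropped with a message.  Failures on
#' individual features are caught and reported as `NA` rows with the
#' failure reason in `status`; the batch never aborts.  Combined
#' p-values receive Benjamini-Hochberg q-values.
#'
#' @param counts non-negative matrix, features x samples, with row and
#'   column names, typically already passed through [filterFeatures()];
#'   alternatively a `SummarizedExperiment` (first assay used, covariates
#'   taken from `colData` when `covariates` is `NULL`).
#' @param covariates data.frame of per-sample covariates, rows keyed by
#'   sample id (rownames matching `colnames(counts)`).
#' @param testCols,adjustCols character vectors naming the covariate
#'   columns under test and the adjustment columns.
#' @param taus,mode,B,control passed to [ziqsirTest()].
#' @param seed master seed for jittering, optimiser starts and
#'   permutations (per-feature seeds are derived deterministically).
#' @param addLibrarySize append the library-size covariate to the
#'   adjustment set.
#' @param alpha unused in testing, retained for reporting convenience.
#' @return data.frame with one row per feature: `feature_id`,
#'   `n_positive`, `zero_prop`, `p_logistic`, one `p_q_<tau>` column per
#'   level, `p_combined`, `q_value`, `status`.
#' @export
runFeatureTests <- function(counts, covariates, testCols, adjustCols,
                            taus = c(0.1, 0.25, 0.5, 0.75, 0.9),
                            mode = "auto", B = 199L, seed = 1,
                            control = ziqControl(),
                            addLibrarySize = TRUE, alpha = 0.05) {
  if (methods::is(counts, "SummarizedExperiment")) {
    if (is.null(covariates))
      covariates <- as.data.frame(SummarizedExperiment::colData(counts))
    counts <- SummarizedExperiment::assay(counts, 1)
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("feature", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) || is.null(rownames(covariates)) ||
      !setequal(colnames(counts), rownames(covariates)))
    stop("sample ids of 'counts' and 'covariates' do not match")
  covariates <- covariates[colnames(counts), , drop = FALSE]
  miss <- names(covariates) %in% c(testCols, adjustCols)
  covariates <- covariates[, miss, drop = FALSE]
  stopifnot(all(testCols %in% names(covariates)),
            all(adjustCols %in% names(covariates)))

  keep <- stats::complete.cases(covariates)
  if (any(!keep)) {
    message(sprintf("dropping %d sample(s) with missing covariates",
                    sum(!keep)))
    covariates <- covariates[keep, , drop = FALSE]
    counts <- counts[, keep, drop = FALSE]
  }
  Z <- .dummyCode(covariates[, testCols, drop = FALSE])
  C <- .dummyCode(covariates[, adjustCols, drop = FALSE])
  if (addLibrarySize)
    C <- cbind(C, librarySize = librarySizeCovariate(counts))

  pqNames <- paste0("p_q_", taus)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    fid <- rownames(counts)[i]
    featSeed <- replicateSeed(seed, i)
    y <- jitterCounts(counts[i, ], seed = featSeed)
    base <- data.frame(feature_id = fid, n_positive = sum(y > 0),
                       zero_prop = mean(y == 0))
    res <- tryCatch(
      ziqsirTest(ziqData(y, Z, C), taus = taus, mode = mode, B = B,
                 seed = featSeed + 1, control = control),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      pq <- as.data.frame(as.list(stats::setNames(rep(NA_real_,
                                                      length(taus)),
                                                  pqNames)))
      cbind(base, p_logistic = NA_real_, pq, p_combined = NA_real_,
            status = res)
    } else {
      pt <- res@perTau
      pv <- if (!is.null(pt$pPermutation)) pt$pPermutation
            else pt$pAsymptotic
      pq <- as.data.frame(as.list(stats::setNames(pv, pqNames)))
      cbind(base, p_logistic = res@pLogistic, pq,
            p_combined = res@pValue, status = "ok")
    }
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_combined)
  out[, c("feature_id", "n_positive", "zero_prop", "p_logistic",
          pqNames, "p_combined", "q_value", "status")]
}
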