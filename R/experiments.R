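## Deterministic per-replicate seed from a master seed (kept < 2^31).
replicateSeed <- function(master, r) {
  (as.numeric(master) * 10007 + 7919 * r) %% 2147483647
}

.runExperiment <- function(setting, n, predictors, replicates, alpha,
                           null, taus, mode, B, seed, control,
                           verbose = FALSE) {
  stopifnot(replicates >= 1, alpha >= 0, alpha <= 1)
  if (!is.list(predictors)) predictors <- list(predictors)
  rows <- lapply(seq_along(predictors), function(j) {
    coords <- as.integer(predictors[[j]])
    rej <- logical(replicates)
    for (r in seq_len(replicates)) {
      s <- replicateSeed(seed, (j - 1) * replicates + r)
      sim <- simulateZiqData(n, setting = setting,
                             nullCoords = if (null) coords else integer(0),
                             seed = s)
      d <- simToZiqData(sim, coords)
      ## convergence-flag warnings from individual replicates are
      ## expected noise at this scale; the flag is kept on the fit
      res <- suppressWarnings(
        ziqsirTest(d, taus = taus, mode = mode, B = B,
                   seed = s + 1, control = control))
      rej[r] <- res@pValue < alpha
      if (verbose && r %% 50 == 0)
        message(sprintf("predictor {%s}: %d/%d replicates",
                        paste(coords, collapse = ","), r, replicates))
    }
    rate <- mean(rej)
    data.frame(predictor = paste(coords, collapse = ","),
               rate = rate,
               se = sqrt(rate * (1 - rate) / replicates),
               replicates = replicates)
  })
  out <- do.call(rbind, rows)
  attr(out, "setting") <- setting
  attr(out, "n") <- n
  attr(out, "alpha") <- alpha
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "type") <- if (null) "typeI" else "power"
  out
}

#' Monte Carlo type-I-error experiment
#'
#' For each predictor set, repeatedly simulates data with that set's
#' presence coefficients and quantile curves zeroed (the null DGP for
#' those coordinates), runs the full test of those coordinates adjusting
#' for the remaining covariates, and reports the rejection fraction at
#' `alpha` with its Monte Carlo standard error
#' \eqn{\sqrt{\hat r(1-\hat r)/R}}.
#'
#' @param setting simulation setting, 1 or 2.
#' @param n per-replicate sample size.
#' @param predictors list of integer coordinate sets (1..5); a single
#'   vector is treated as one set.
#' @param replicates Monte Carlo replicate count.
#' @param alpha nominal level.
#' @param taus quantile grid.
#' @param mode,B,control passed to [ziqsirTest()].
#' @param seed master seed; replicate seeds are derived from it by a
#'   deterministic counter scheme.
#' @param verbose emit progress messages.
#' @return data.frame with columns `predictor`, `rate`, `se`,
#'   `replicates`, plus experiment metadata in attributes.
#' @export
typeIErrorExperiment <- function(setting, n, predictors,
                                 replicates = 500, alpha = 0.05,
                                 taus = c(0.1, 0.25, 0.5, 0.75, 0.9),
                                 mode = "auto", B = 199L, seed = 1,
                                 control = ziqControl(),
                                 verbose = FALSE) {
  .runExperiment(setting, n, predictors, replicates, alpha, null = TRUE,
                 taus = taus, mode = mode, B = B, seed = seed,
                 control = control, verbose = verbose)
}

#' Monte Carlo power experiment
#'
#' As [typeIErrorExperiment()], but data are generated from the full
#' (alternative) DGP with no coefficients zeroed.
#'
#' @inheritParams typeIErrorExperiment
#' @return data.frame as in [typeIErrorExperiment()].
#' @export
powerExperiment <- function(setting, n, predictors, replicates = 500,
                            alpha = 0.05,
                            taus = c(0.1, 0.25, 0.5, 0.75, 0.9),
                            mode = "auto", B = 199L, seed = 1,
                            control = ziqControl(), verbose = FALSE) {
  .runExperiment(setting, n, predictors, replicates, alpha, null = FALSE,
                 taus = taus, mode = mode, B = B, seed = seed,
                 control = control, verbose = verbose)
}
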