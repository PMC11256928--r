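#' Bootstrap variability of the estimated FDR threshold
#'
#' Resamples spectra (paired top/second score rows, preserving missingness)
#' with replacement, recomputes the missing-score proportion, refits the
#' mixture on each replicate and inverts the FDR threshold at `alpha`. The
#' resampling unit is the spectrum, matching a bootstrap over the original
#' mass spectra. Replicate fits use reduced restarts by default
#' (configurable through `fit_config`) and may be warm-started from a
#' full-data fit.
#'
#' @param ds a [score_dataset()].
#' @param B number of bootstrap replicates.
#' @param alpha FDR level whose threshold is studied.
#' @param fit_config named list of arguments passed to [fit_xl_mixture()]
#'   (e.g. `n_restarts`, `max_iter`, `tol`, `init_models`, `control`);
#'   defaults to 24 restarts.
#' @param seed integer seed; replicate resampling and fitting are
#'   deterministic given it.
#' @param resample set to `FALSE` to refit the original data in every
#'   replicate (identity resample; testing hook).
#' @return An object of class `"xl_bootstrap"`: `thresholds` (length `B`
#'   minus failures, `NA`-free), `alpha`, `B`, `failures` (count), and
#'   `summary` with the median and IQR of the thresholds.
#' @export
bootstrap_thresholds <- function(ds, B = 50L, alpha = 0.01,
                                 fit_config = list(), seed = 1L,
                                 resample = TRUE) {
  stopifnot(inherits(ds, "score_dataset"), nrow(ds) >= 1L, B >= 1L)
  cfg <- utils::modifyList(list(n_restarts = 24L), fit_config)
  n <- nrow(ds)
  thresholds <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- if (resample) {
      with_seed(child_seed(seed, 1000L + b), sample.int(n, n, replace = TRUE))
    } else {
      seq_len(n)
    }
    rep_ds <- score_dataset(ds$s1[idx], ds$s2[idx], check_order = FALSE)
    args <- c(list(ds = rep_ds, seed = child_seed(seed, b)), cfg)
    fit <- tryCatch(do.call(fit_xl_mixture, args), error = function(e) NULL)
    if (!is.null(fit))
      thresholds[b] <- fdr_threshold(fit$model, alpha)
  }
  ok <- thresholds[!is.na(thresholds)]
  structure(list(thresholds = ok, alpha = alpha, B = B,
                 failures = sum(is.na(thresholds)),
                 summary = c(median = stats::median(ok),
                             IQR = stats::IQR(ok))),
            class = "xl_bootstrap")
}

#' @export
print.xl_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap of the %.3g%% FDR threshold: %d/%d replicates succeeded\n",
    100 * x$alpha, length(x$thresholds), x$B))
  cat(sprintf("  median = %.4f, IQR = %.4f\n",
              x$summary[["median"]], x$summary[["IQR"]]))
  invisible(x)
}
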