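#' Model-based FDR estimate at a score threshold
#'
#' For a fitted mixture model the estimated FDR among top PSMs accepted at
#' threshold `tau` is the incorrect-plus-partially-incorrect share of the
#' top-score survival mass:
#' `(wI1*S(tau; I1) + wJ1*S(tau; J1)) / (wC*S(tau; C) + wI1*S(tau; I1) + wJ1*S(tau; J1))`,
#' with `S` the skew-normal survival function (computed through Owen's T).
#' Where every survival underflows (far right tail) the estimate returns the
#' analytic limit 0, which is the limit under the enforced dominance chain
#' (the correct component has the slowest right-tail decay).
#'
#' @param model a [two_sample_model()] or [one_sample_model()].
#' @param tau numeric vector of score thresholds.
#' @return Numeric vector of FDR estimates in `[0, 1]`.
#' @export
mixture_fdr <- function(model, tau) {
  stopifnot(inherits(model, c("two_sample_model", "one_sample_model")))
  sC <- ssn(tau, model$theta$C)
  sJ <- ssn(tau, model$theta$J1)
  sI <- ssn(tau, model$theta$I1)
  num <- model$w[["I1"]] * sI + model$w[["J1"]] * sJ
  den <- model$w[["C"]] * sC + num
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, 0), 1)
}

model_score_range <- function(model) {
  mus <- vapply(model$theta, function(p) p$mu, numeric(1))
  sds <- vapply(model$theta, function(p) p$sigma, numeric(1))
  c(min(mus - 8 * sds), max(mus + 10 * sds))
}

#' Score threshold attaining a target FDR
#'
#' Inverts [mixture_fdr()] by the monotone envelope: the smallest threshold
#' `tau` such that the estimated FDR is at most `alpha` at `tau` and at
#' every larger threshold. The envelope (running maximum from the right) is
#' used because the raw estimate can be locally non-monotone where the
#' survival functions underflow. The crossing is located on a fine grid and
#' refined by bisection.
#'
#' @param model a fitted mixture model.
#' @param alpha target FDR level in (0, 1), e.g. 0.01.
#' @param range optional score interval to search; defaults to the model's
#'   effective support.
#' @param grid_size number of grid points.
#' @return The threshold score; the lower end of `range` when the FDR is
#'   at most `alpha` everywhere, or `NA` when `alpha` is unattainable.
#' @export
fdr_threshold <- function(model, alpha = 0.01, range = NULL,
                          grid_size = 4096L) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(range)) range <- model_score_range(model)
  xs <- seq(range[1L], range[2L], length.out = grid_size)
  fdr <- mixture_fdr(model, xs)
  env <- rev(cummax(rev(fdr)))   # sup of fdr over thresholds >= tau
  ok <- which(env <= alpha)
  if (!length(ok)) return(NA_real_)
  i <- ok[1L]
  if (i == 1L) return(xs[1L])
  lo <- xs[i - 1L]; hi <- xs[i]
  target_tol <- 1e-6 * diff(range)
  while (hi - lo > target_tol) {
    mid <- (lo + hi) / 2
    if (mixture_fdr(model, mid) <= alpha) hi <- mid else lo <- mid
  }
  hi
}

#' FDR curve over a score grid
#'
#' Evaluates the model-based FDR estimate and the number of identified
#' spectra (top scores at or above the threshold) over a grid spanning the
#' observed top scores.
#'
#' @param model a fitted mixture model.
#' @param ds a [score_dataset()] supplying the identification counts.
#' @param grid_size number of thresholds.
#' @return A data frame of class `"fdr_curve"` with columns `tau`,
#'   `fdr_est`, `n_identified`.
#' @export
fdr_curve <- function(model, ds, grid_size = 512L) {
  stopifnot(inherits(ds, "score_dataset"), nrow(ds) >= 1L)
  xs <- seq(min(ds$s1), max(ds$s1), length.out = grid_size)
  n_id <- vapply(xs, function(t) sum(ds$s1 >= t), numeric(1))
  out <- data.frame(tau = xs, fdr_est = mixture_fdr(model, xs),
                    n_identified = as.integer(n_id))
  class(out) <- c("fdr_curve", "data.frame")
  out
}

#' Target-decoy counts above a threshold
#'
#' Counts, among top PSMs with score at or above `tau`, those with both
#' peptides matched to target sequences (`TT`), exactly one matched to a
#' decoy (`TD`), and both matched to decoys (`DD`).
#'
#' @param psms data frame with columns `score` (numeric) and `label`
#'   (factor/character in `TT`, `TD`, `DD`).
#' @param tau score threshold.
#' @return A list with integer counts `TT`, `TD`, `DD`.
#' @export
tda_counts <- function(psms, tau) {
  stopifnot(is.data.frame(psms), nrow(psms) >= 1L,
            all(c("score", "label") %in% names(psms)))
  if (!all(psms$label %in% c("TT", "TD", "DD")))
    stop("labels must be TT, TD or DD")
  keep <- psms$score >= tau
  list(TT = sum(keep & psms$label == "TT"),
       TD = sum(keep & psms$label == "TD"),
       DD = sum(keep & psms$label == "DD"))
}

#' Target-decoy FDR estimate
#'
#' The XL-MS/MS target-decoy estimator `(TD - DD) / TT`. The estimate can
#' be negative or exceed 1; it is returned unclamped, with attribute
#' `"out_of_range"` flagging estimates outside `[0, 1]`.
#'
#' @param counts a list with `TT`, `TD`, `DD` (see [tda_counts()]).
#' @return The estimate, with logical attribute `out_of_range`.
#' @export
tda_fdr <- function(counts) {
  stopifnot(all(c("TT", "TD", "DD") %in% names(counts)))
  if (counts$TT < 1) stop("tda_fdr undefined: TT = 0 above the threshold")
  est <- (counts$TD - counts$DD) / counts$TT
  attr(est, "out_of_range") <- est < 0 || est > 1
  est
}

#' Target-decoy threshold attaining a target FDR
#'
#' The smallest observed score `tau` such that the target-decoy estimate is
#' at most `alpha` at `tau` and at every larger observed score (monotone
#' envelope over the distinct observed scores).
#'
#' @inheritParams tda_counts
#' @param alpha target FDR level.
#' @return The threshold score, or `NA` when unattainable.
#' @export
tda_threshold <- function(psms, alpha = 0.01) {
  stopifnot(is.data.frame(psms), nrow(psms) >= 1L)
  taus <- sort(unique(psms$score))
  est <- vapply(taus, function(t) {
    ct <- tda_counts(psms, t)
    if (ct$TT < 1) Inf else (ct$TD - ct$DD) / ct$TT
  }, numeric(1))
  env <- rev(cummax(rev(est)))
  ok <- which(env <= alpha)
  if (!length(ok)) return(NA_real_)
  taus[ok[1L]]
}
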