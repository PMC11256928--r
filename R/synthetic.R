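# Labelled synthetic-data generators. Two deliberately different samplers:
# the mixture-faithful sampler draws scores exactly from the model the
# fitting algorithm assumes (so parameter recovery can be tested against
# known truth), while the competition sampler draws per-spectrum candidate
# scores and takes maxima, reproducing the order-statistic process the
# mixture model only approximates (so FDR calibration can be tested under
# realistic misspecification).

#' Labelled synthetic score dataset
#'
#' @param s1,s2 top and second scores (`s2` may be `NA`).
#' @param label1 generating component of `s1` (`C`, `J1`, `I1`).
#' @param label2 generating component of `s2`, `NA` when `s2` missing.
#' @param check_order enforce the within-spectrum ordering `s2 <= s1`.
#' @return An object of class `"labeled_dataset"` extending
#'   [score_dataset()] with columns `label1`, `label2`.
#' @export
labeled_dataset <- function(s1, s2, label1, label2, check_order = TRUE) {
  ds <- score_dataset(s1, s2, check_order = check_order)
  stopifnot(length(label1) == nrow(ds), length(label2) == nrow(ds),
            all(label1 %in% TOP_COMPONENTS),
            all(is.na(label2) | label2 %in% ALL_COMPONENTS),
            all(is.na(s2) == is.na(label2)))
  ds$label1 <- as.character(label1)
  ds$label2 <- as.character(label2)
  class(ds) <- c("labeled_dataset", class(ds))
  ds
}

#' Strip ground-truth labels
#'
#' @param ds a [labeled_dataset()].
#' @return The underlying [score_dataset()].
#' @export
strip_labels <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  score_dataset(ds$s1, ds$s2, check_order = FALSE)
}

#' Sample a labelled dataset exactly from the two-sample mixture
#'
#' Top scores are drawn from the three-component mixture with component
#' labels multinomial in `w`; second scores are missing with probability
#' `v_phi` and otherwise drawn from the five-component mixture with labels
#' multinomial in `v`. Because the sampler matches the fitted model's
#' assumptions exactly, fitting this data tests parameter recovery.
#'
#' @param model a [two_sample_model()] (should satisfy the dominance chain).
#' @param n number of spectra.
#' @param seed integer seed.
#' @return A [labeled_dataset()].
#' @export
sample_mixture_faithful <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "two_sample_model"), n >= 1)
  with_seed(seed, {
    lab1 <- sample(TOP_COMPONENTS, n, replace = TRUE, prob = model$w)
    s1 <- numeric(n)
    for (nm in TOP_COMPONENTS) {
      idx <- lab1 == nm
      if (any(idx)) s1[idx] <- rsn(sum(idx), model$theta[[nm]])
    }
    miss <- stats::runif(n) < model$v_phi
    lab2 <- rep(NA_character_, n)
    s2 <- rep(NA_real_, n)
    n_obs <- sum(!miss)
    if (n_obs) {
      lab2[!miss] <- sample(ALL_COMPONENTS, n_obs, replace = TRUE,
                            prob = model$v)
      for (nm in ALL_COMPONENTS) {
        idx <- !is.na(lab2) & lab2 == nm
        if (any(idx)) s2[idx] <- rsn(sum(idx), model$theta[[nm]])
      }
    }
    # the two marginals are drawn independently, so the per-row ordering
    # s2 <= s1 is not enforced; the fit uses the marginals only
    labeled_dataset(s1, s2, lab1, lab2, check_order = FALSE)
  })
}

#' Sample a labelled dataset from the per-spectrum competition process
#'
#' Emulates the latent structure behind the mixture model: per spectrum a
#' correct-match score `c ~ SN(theta_C)` is present with probability
#' `rho_correct`; ordered partially incorrect scores `(j1, j2)` are drawn
#' with `j1 ~ SN(theta_J1)` and `j2 ~ SN(theta_J2)` conditioned on
#' `j2 <= j1` (rejection), and ordered incorrect scores `(i1, i2)`
#' analogously. The top score is the maximum of the present candidates; the
#' runner-up follows the latent case analysis (`s1 = C` leaves
#' `max(j1, i1)`; `s1 = J1` leaves `max(c, j2, i1)`; `s1 = I1` leaves
#' `max(c, j1, i2)`). Second scores are then set missing with probability
#' `plogis(missing_intercept - missing_slope * s1)`, so that with a positive
#' slope missingness concentrates in the left tail of the top scores, as
#' observed in real searches.
#'
#' @param theta named list of [sn_params()] for all five components
#'   (chain-feasible).
#' @param rho_correct probability that a spectrum has a correct candidate.
#' @param missing_intercept,missing_slope logistic missingness parameters
#'   (`missing_slope >= 0`).
#' @param n number of spectra.
#' @param seed integer seed.
#' @return A [labeled_dataset()].
#' @export
sample_competition <- function(theta, rho_correct,
                               missing_intercept = -Inf, missing_slope = 0,
                               n = 1000L, seed = NULL) {
  stopifnot(all(ALL_COMPONENTS %in% names(theta)),
            rho_correct >= 0, rho_correct <= 1, missing_slope >= 0, n >= 1)
  with_seed(seed, {
    draw_ordered <- function(p_top, p_second) {
      top <- rsn(n, p_top)
      second <- rsn(n, p_second)
      bad <- which(second > top)
      if (length(bad) > 0.99 * n)
        stop("sample_competition: rejection sampling failing; component ",
             "parameters make second > top nearly certain")
      tries <- 0L
      while (length(bad) && tries < 50L) {
        second[bad] <- rsn(length(bad), p_second)
        bad <- bad[second[bad] > top[bad]]
        tries <- tries + 1L
      }
      if (length(bad)) {
        # stubborn pairs (top deep in the second component's left tail):
        # draw the conditional law exactly by inverse-CDF bisection
        u <- stats::runif(length(bad)) * psn(top[bad], p_second)
        lo <- rep(p_second$mu - 14 * p_second$sigma, length(bad))
        lo <- pmin(lo, top[bad] - 1)
        hi <- top[bad]
        for (it in 1:60) {
          mid <- (lo + hi) / 2
          below <- psn(mid, p_second) < u
          lo[below] <- mid[below]
          hi[!below] <- mid[!below]
        }
        second[bad] <- (lo + hi) / 2
      }
      list(top = top, second = second)
    }
    has_c <- stats::runif(n) < rho_correct
    cs <- ifelse(has_c, rsn(n, theta$C), -Inf)
    js <- draw_ordered(theta$J1, theta$J2)
    is_ <- draw_ordered(theta$I1, theta$I2)
    top_mat <- cbind(C = cs, J1 = js$top, I1 = is_$top)
    k <- max.col(top_mat, ties.method = "first")
    lab1 <- TOP_COMPONENTS[k]
    s1 <- top_mat[cbind(seq_len(n), k)]
    ru_mat <- cbind(
      C  = ifelse(lab1 == "J1" | lab1 == "I1", cs, -Inf),
      J1 = ifelse(lab1 != "J1", js$top, -Inf),
      J2 = ifelse(lab1 == "J1", js$second, -Inf),
      I1 = ifelse(lab1 != "I1", is_$top, -Inf),
      I2 = ifelse(lab1 == "I1", is_$second, -Inf))
    k2 <- max.col(ru_mat, ties.method = "first")
    lab2 <- ALL_COMPONENTS[k2]
    s2 <- ru_mat[cbind(seq_len(n), k2)]
    none <- !is.finite(s2)
    miss <- none | stats::runif(n) <
      stats::plogis(missing_intercept - missing_slope * s1)
    s2[miss] <- NA_real_
    lab2[miss] <- NA_character_
    labeled_dataset(s1, s2, lab1, lab2)
  })
}

#' Ground-truth FDR of a labelled dataset
#'
#' Among spectra with top score at or above `tau`, the fraction whose top
#' score did not come from the correct component; 0 when none pass.
#'
#' @param ds a [labeled_dataset()].
#' @param tau numeric vector of thresholds.
#' @return Numeric vector of true false-discovery proportions.
#' @export
true_fdr <- function(ds, tau) {
  stopifnot(inherits(ds, "labeled_dataset"))
  vapply(tau, function(t) {
    keep <- ds$s1 >= t
    if (!any(keep)) return(0)
    mean(ds$label1[keep] != "C")
  }, numeric(1))
}

#' Sample a labelled target-decoy PSM set
#'
#' Generates top-PSM scores under the exchangeability assumption of the
#' target-decoy approach: a fraction `prop_correct` of spectra have a
#' correct match (label `TT`, score from `theta_correct`); the rest are
#' incorrect matches (score from `theta_incorrect`) whose two peptides
#' independently hit a decoy sequence with probability `decoy_fraction`,
#' giving labels `TT`, `TD`, `DD` with probabilities `(1-d)^2`, `2d(1-d)`,
#' `d^2`.
#'
#' @param theta_correct,theta_incorrect [sn_params()] for correct and
#'   incorrect score distributions.
#' @param n number of spectra.
#' @param prop_correct fraction of spectra with a correct match.
#' @param decoy_fraction probability that an incorrect peptide is a decoy
#'   (0.5 for an equal-size target-decoy database).
#' @param seed integer seed.
#' @return A data frame with columns `score`, `label` and logical
#'   `correct` (the ground truth).
#' @export
sample_tda <- function(theta_correct, theta_incorrect, n,
                       prop_correct = 0.3, decoy_fraction = 0.5,
                       seed = NULL) {
  stopifnot(n >= 1, prop_correct >= 0, prop_correct <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  with_seed(seed, {
    correct <- stats::runif(n) < prop_correct
    score <- numeric(n)
    score[correct] <- rsn(sum(correct), theta_correct)
    score[!correct] <- rsn(sum(!correct), theta_incorrect)
    label <- rep("TT", n)
    n_inc <- sum(!correct)
    if (n_inc) {
      d <- decoy_fraction
      label[!correct] <- sample(c("TT", "TD", "DD"), n_inc, replace = TRUE,
                                prob = c((1 - d)^2, 2 * d * (1 - d), d^2))
    }
    data.frame(score = score, label = label, correct = correct)
  })
}

#' Default synthetic scenario
#'
#' A chain-feasible two-sample model whose morphology matches typical
#' XL-MS/MS search-score fits: five left-to-right ordered skew-normal
#' components on an arbitrary score scale, the correct component rightmost
#' and right-skewed, the others left-skewed with scale and skewness varying
#' down the chain (components of identical shape would make the mixture
#' non-identifiable); a minority of correct top hits; a small correct share
#' in the second scores; a quarter of the spectra missing their second
#' score.
#'
#' @param v_phi missing-second-score proportion.
#' @return A [two_sample_model()].
#' @export
default_scenario <- function(v_phi = 0.25) {
  theta <- list(
    C  = sn_params(34, 4.5, 1.5),
    J1 = sn_params(27, 4.2, -0.8),
    J2 = sn_params(22.5, 4.8, -1.2),
    I1 = sn_params(18, 5.2, -1.8),
    I2 = sn_params(13, 5.8, -2.5))
  two_sample_model(
    theta,
    w = c(C = 0.31, J1 = 0.27, I1 = 0.42),
    v = c(C = 0.02, J1 = 0.19, J2 = 0.22, I1 = 0.35, I2 = 0.22),
    v_phi = v_phi)
}
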