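check_simplex <- function(x, nm, tol = 1e-8) {
  if (!all(nm %in% names(x)))
    stop("weights must be named with: ", paste(nm, collapse = ", "))
  x <- x[nm]
  if (any(x <= 0)) stop("weights must be strictly positive")
  if (abs(sum(x) - 1) > tol) stop("weights must sum to 1")
  x / sum(x)
}

#' Two-sample skew-normal mixture model
#'
#' The top score `S1` is modelled as a three-component SN mixture over the
#' correct (`C`), top partially incorrect (`J1`) and top incorrect (`I1`)
#' latent matches; the second score `S2` as a five-component mixture adding
#' the runner-up partially incorrect (`J2`) and incorrect (`I2`) matches.
#' The `C`, `J1`, `I1` component parameters are shared between the two
#' mixtures, which is what lets the second sample inform the fit.
#'
#' @param theta named list of [sn_params()] for components
#'   `C`, `J1`, `J2`, `I1`, `I2`.
#' @param w mixing weights of `S1` over `C`, `J1`, `I1` (positive, sum 1).
#' @param v mixing weights of `S2` over all five components.
#' @param v_phi fraction of spectra with missing second scores, a constant
#'   of the dataset the model was (or will be) fitted to.
#' @return An object of class `"two_sample_model"`.
#' @export
two_sample_model <- function(theta, w, v, v_phi = 0) {
  if (!all(ALL_COMPONENTS %in% names(theta)))
    stop("'theta' must contain components: ",
         paste(ALL_COMPONENTS, collapse = ", "))
  theta <- theta[ALL_COMPONENTS]
  stopifnot(all(vapply(theta, inherits, logical(1), "sn_params")),
            is.numeric(v_phi), length(v_phi) == 1L,
            v_phi >= 0, v_phi <= 1)
  structure(list(theta = theta,
                 w = check_simplex(w, TOP_COMPONENTS),
                 v = check_simplex(v, ALL_COMPONENTS),
                 v_phi = as.numeric(v_phi)),
            class = "two_sample_model")
}

#' One-sample skew-normal mixture model
#'
#' Three-component mixture for the top score only; used as the baseline
#' model that ignores second-ranked PSMs.
#'
#' @param theta named list of [sn_params()] for `C`, `J1`, `I1`.
#' @param w mixing weights over `C`, `J1`, `I1`.
#' @return An object of class `"one_sample_model"`.
#' @export
one_sample_model <- function(theta, w) {
  if (!all(TOP_COMPONENTS %in% names(theta)))
    stop("'theta' must contain components: ",
         paste(TOP_COMPONENTS, collapse = ", "))
  theta <- theta[TOP_COMPONENTS]
  stopifnot(all(vapply(theta, inherits, logical(1), "sn_params")))
  structure(list(theta = theta, w = check_simplex(w, TOP_COMPONENTS)),
            class = "one_sample_model")
}

#' @export
print.two_sample_model <- function(x, ...) {
  cat("Two-sample skew-normal mixture model\n")
  for (nm in ALL_COMPONENTS) {
    p <- x$theta[[nm]]
    cat(sprintf("  %-3s mu=%8.4f sigma=%7.4f lambda=%8.4f  w=%s v=%.4f\n",
                nm, p$mu, p$sigma, p$lambda,
                if (nm %in% TOP_COMPONENTS) sprintf("%.4f", x$w[[nm]])
                else "   -  ",
                x$v[[nm]]))
  }
  cat(sprintf("  v_phi = %.4f\n", x$v_phi))
  invisible(x)
}

#' @export
print.one_sample_model <- function(x, ...) {
  cat("One-sample skew-normal mixture model\n")
  for (nm in TOP_COMPONENTS) {
    p <- x$theta[[nm]]
    cat(sprintf("  %-3s mu=%8.4f sigma=%7.4f lambda=%8.4f  w=%.4f\n",
                nm, p$mu, p$sigma, p$lambda, x$w[[nm]]))
  }
  invisible(x)
}

# n x k matrix of component log-densities.
comp_logdens <- function(theta, comps, x) {
  m <- vapply(comps, function(nm)
    cpp_sn_logpdf(x, theta[[nm]]$mu, theta[[nm]]$sigma, theta[[nm]]$lambda),
    numeric(length(x)))
  if (length(x) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, comps))
  m
}

# E-step over one sample via the compiled kernel: responsibilities plus the
# sample's (multiplicity-weighted) log-likelihood contribution in one pass.
estep_sample <- function(theta, comps, x, wts, mult = rep(1, length(x))) {
  res <- cpp_estep(x,
                   vapply(theta[comps], `[[`, numeric(1), "mu"),
                   vapply(theta[comps], `[[`, numeric(1), "sigma"),
                   vapply(theta[comps], `[[`, numeric(1), "lambda"),
                   log(wts[comps]), mult)
  colnames(res$resp) <- comps
  res
}

logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# Observed score vectors plus per-observation multiplicities (unit for raw
# data; counts when the dataset carries binned-score weight attributes).
model_samples <- function(model, ds) {
  obs <- !is.na(ds$s2)
  w1 <- attr(ds, "wt1"); w2 <- attr(ds, "wt2")
  list(s1 = ds$s1, s2 = ds$s2[obs],
       w1 = if (is.null(w1)) rep(1, nrow(ds)) else w1,
       w2 = if (is.null(w2)) rep(1, sum(obs)) else w2[obs])
}

#' Observed-data log-likelihood
#'
#' Sum over all top scores of the log three-component mixture density plus
#' the sum over observed second scores of the log five-component mixture
#' density. Spectra with a missing second score contribute only through
#' their top score. All mixture evaluations use log-sum-exp.
#'
#' @param model a [two_sample_model()] or [one_sample_model()].
#' @param ds a [score_dataset()].
#' @return A finite scalar log-likelihood.
#' @export
loglik <- function(model, ds) {
  stopifnot(inherits(ds, "score_dataset"))
  sm <- model_samples(model, ds)
  l1 <- comp_logdens(model$theta, TOP_COMPONENTS, sm$s1)
  l1 <- sweep(l1, 2L, log(model$w), `+`)
  total <- sum(sm$w1 * logsumexp_rows(l1))
  if (inherits(model, "two_sample_model") && length(sm$s2)) {
    l2 <- comp_logdens(model$theta, ALL_COMPONENTS, sm$s2)
    l2 <- sweep(l2, 2L, log(model$v), `+`)
    total <- total + sum(sm$w2 * logsumexp_rows(l2))
  }
  total
}

#' Posterior component responsibilities
#'
#' For each top score, the posterior probability that it arose from each of
#' `C`, `J1`, `I1` (`omega`); for each observed second score, the posterior
#' over all five components (`nu`). These realize the conditional
#' expectations of the hidden component indicators in the EM framework.
#' Computed in log space; rows sum to 1.
#'
#' @inheritParams loglik
#' @return A list with matrices `omega` (`n1` x 3) and, for a two-sample
#'   model, `nu` (`n2_observed` x 5).
#' @export
responsibilities <- function(model, ds) {
  stopifnot(inherits(ds, "score_dataset"))
  sm <- model_samples(model, ds)
  l1 <- comp_logdens(model$theta, TOP_COMPONENTS, sm$s1)
  l1 <- sweep(l1, 2L, log(model$w), `+`)
  omega <- exp(l1 - logsumexp_rows(l1))
  out <- list(omega = omega)
  if (inherits(model, "two_sample_model")) {
    if (length(sm$s2)) {
      l2 <- comp_logdens(model$theta, ALL_COMPONENTS, sm$s2)
      l2 <- sweep(l2, 2L, log(model$v), `+`)
      out$nu <- exp(l2 - logsumexp_rows(l2))
    } else {
      out$nu <- matrix(numeric(0), 0L, length(ALL_COMPONENTS),
                       dimnames = list(NULL, ALL_COMPONENTS))
    }
  }
  out
}

# q(s, t, tau, theta) of the complete-data log-likelihood, with theta in
# alternate form: log Gamma + ((s-mu)^2 - 2(s-mu) Delta t + (Delta^2+Gamma) tau)/Gamma
q_kernel <- function(s, t, tau, alt) {
  log(alt$Gamma) +
    ((s - alt$mu)^2 - 2 * (s - alt$mu) * alt$Delta * t +
       (alt$Delta^2 + alt$Gamma) * tau) / alt$Gamma
}

#' EM Q-function of the two-sample model
#'
#' Conditional expectation of the complete-data log-likelihood of `new`
#' given the observed scores, taken under the current model `cur` (which
#' supplies the responsibilities and the conditional truncated-normal
#' moments).
#'
#' @param new,cur [two_sample_model()] objects (candidate and current).
#' @param ds a [score_dataset()].
#' @return Scalar value of the Q-function (up to the additive constant
#'   dropped from the complete-data log-likelihood).
#' @export
q_function <- function(new, cur, ds) {
  stopifnot(inherits(new, "two_sample_model"),
            inherits(cur, "two_sample_model"))
  sm <- model_samples(cur, ds)
  resp <- responsibilities(cur, ds)
  total <- 0
  for (nm in TOP_COMPONENTS) {
    mo <- tn_moments(sm$s1, cur$theta[[nm]])
    qv <- q_kernel(sm$s1, mo$xi1, mo$xi2, to_alternate(new$theta[[nm]]))
    total <- total + sum(resp$omega[, nm] * (log(new$w[[nm]]) - qv / 2))
  }
  if (length(sm$s2)) {
    for (nm in ALL_COMPONENTS) {
      mo <- tn_moments(sm$s2, cur$theta[[nm]])
      qv <- q_kernel(sm$s2, mo$xi1, mo$xi2, to_alternate(new$theta[[nm]]))
      total <- total + sum(resp$nu[, nm] * (log(new$v[[nm]]) - qv / 2))
    }
  }
  total
}
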