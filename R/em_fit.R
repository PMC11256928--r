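# Constrained ECM fitting of the one- and two-sample skew-normal mixtures.
#
# Each iteration: (E) compute responsibilities and the conditional
# truncated-normal moments under the current parameters; (CM) update each
# component's (mu, Delta, Gamma) in that order with closed forms, passing
# every candidate through binary-search repair against the density-dominance
# chain; (CM) update the mixing weights by solving the KKT system of the
# weight part of the Q-function under constraint set B, with a greedy
# active-set search.

default_control <- function(control = list()) {
  ctrl <- list(n_grid = 96L,         # dominance grid inside the ECM loop
               repair_iter = 12L,    # bisection steps in constraint repair
               freeze_tol = 1e-10,   # responsibility mass below which a
                                     # component is frozen for the iteration
               weight_floor = 1e-12,
               kkt_tol = 1e-10,
               kkt_max_iter = 200L)
  ctrl[names(control)] <- control
  ctrl
}

# ---------------------------------------------------------------------------
# Component-parameter conditional maximization

# Gradient coefficients of the set-B slacks (order b1..b8) with respect to w
# (columns C, J1, I1) and to v' = (1-v_phi) v (columns C, J1, J2, I1, I2).
B_COEF_W <- rbind(
  b1 = c(-1,  0,  0), b2 = c(0, -1,  0), b3 = c(0,  0, -1),
  b4 = c(0,  1,  1),  b5 = c(1,  0,  1), b6 = c(1,  1,  0),
  b7 = c(0,  1,  0),  b8 = c(0,  0,  1))
B_COEF_VP <- rbind(
  b1 = c(0,  1,  0,  1,  0), b2 = c(1,  0,  1,  1,  0),
  b3 = c(1,  1,  0,  0,  1), b4 = c(-1, 0,  0,  0,  0),
  b5 = c(0, -1,  0,  0,  0), b6 = c(0,  0,  0, -1,  0),
  b7 = c(0,  0, -1,  0,  0), b8 = c(0,  0,  0,  0, -1))
B_CONST <- c(b1 = 1, b2 = 1, b3 = 1, b4 = 0, b5 = 0, b6 = 0, b7 = 0, b8 = 0)
colnames(B_COEF_W) <- TOP_COMPONENTS
colnames(B_COEF_VP) <- ALL_COMPONENTS

# Repair one parameter against the dominance pairs involving the component,
# reusing cached modes; the mode of a location-shifted component is the
# shifted mode, so mu-updates need no numeric mode search.
repair_param <- function(theta, modes, component, param, candidate,
                         pairs, ctrl) {
  involved <- pairs_involving(pairs, component)
  p_old <- theta[[component]]
  old <- if (param == "mu") p_old$mu else to_alternate(p_old)[[param]]
  eval_at <- function(value) {
    if (param != "mu") {
      a <- to_alternate(p_old)
      a[[param]] <- value
      if (a$Gamma <= 0) return(NULL)
      p_new <- from_alternate(a)
    } else {
      p_new <- sn_params(value, p_old$sigma, p_old$lambda)
    }
    th <- theta
    th[[component]] <- p_new
    md <- modes
    md[[component]] <- if (param == "mu") modes[[component]] + (value - old)
                       else sn_mode(p_new)
    for (pr in involved) {
      if (!check_dominance(th[[pr[1L]]], th[[pr[2L]]],
                           mode_f = md[[pr[1L]]], mode_g = md[[pr[2L]]],
                           n_grid = ctrl$n_grid))
        return(NULL)
    }
    list(theta = th, modes = md)
  }
  res <- eval_at(candidate)
  if (!is.null(res)) return(c(res, list(value = candidate, repaired = FALSE)))
  lo <- 0; hi <- 1; best <- NULL
  for (i in seq_len(ctrl$repair_iter)) {
    mid <- (lo + hi) / 2
    res <- eval_at(old + mid * (candidate - old))
    if (!is.null(res)) { lo <- mid; best <- res } else hi <- mid
  }
  if (is.null(best)) {
    # no feasible interior point found: keep the current (feasible) value
    best <- list(theta = theta, modes = modes)
    lo <- 0
  }
  c(best, list(value = old + lo * (candidate - old), repaired = TRUE))
}

# Closed-form conditional-maximization update of one component, with repair.
# `rw` and `ss` are the concatenated responsibility weights and scores over
# the samples the component participates in; `theta_bar` is the component's
# iteration-start parameters (used for the moments), `theta`/`modes` the
# current (possibly partially updated) parameter context.
update_one_component <- function(component, rw, ss, theta_bar, theta, modes,
                                 pairs, ctrl, trace = FALSE) {
  mass <- sum(rw)
  if (mass < ctrl$freeze_tol)
    return(list(theta = theta, modes = modes, frozen = TRUE,
                trace = if (trace) list()))
  tr <- list()
  mo <- tn_moments(ss, theta_bar)
  Delta_bar <- to_alternate(theta_bar)$Delta

  mu_hat <- sum(rw * (ss - Delta_bar * mo$xi1)) / mass
  r <- repair_param(theta, modes, component, "mu", mu_hat, pairs, ctrl)
  theta <- r$theta; modes <- r$modes
  mu_new <- r$value
  if (trace) tr$mu <- theta

  Delta_hat <- sum(rw * mo$xi1 * (ss - mu_new)) / sum(rw * mo$xi2)
  r <- repair_param(theta, modes, component, "Delta", Delta_hat, pairs, ctrl)
  theta <- r$theta; modes <- r$modes
  Delta_new <- r$value
  if (trace) tr$Delta <- theta

  g <- (ss - mu_new)^2 - 2 * Delta_new * mo$xi1 * (ss - mu_new) +
    Delta_new^2 * mo$xi2
  Gamma_hat <- sum(rw * g) / mass
  r <- repair_param(theta, modes, component, "Gamma", Gamma_hat, pairs, ctrl)
  if (trace) tr$Gamma <- r$theta
  list(theta = r$theta, modes = r$modes, frozen = FALSE,
       trace = if (trace) tr)
}

#' One constrained ECM update of a single component
#'
#' Updates the skew-normal parameters of one mixture component from the
#' current responsibilities, in the order location, then `Delta`, then
#' `Gamma` (each conditional maximum uses the parameters updated before it),
#' passing every candidate through binary-search repair against the density
#' dominance chain. Shared components (`C`, `J1`, `I1` of a two-sample
#' model) pool both samples; `J2` and `I2` use the second sample only.
#'
#' @param component component name.
#' @param ds a [score_dataset()].
#' @param resp responsibilities computed from `model` (see
#'   [responsibilities()]).
#' @param model the current [two_sample_model()] or [one_sample_model()].
#' @param control list of control parameters (see package vignette).
#' @param trace return the full parameter map after each of the three
#'   single-parameter commits instead of only the final parameters.
#' @return The updated [sn_params()] for `component`, or (with
#'   `trace = TRUE`) a list of the parameter maps after the `mu`, `Delta`
#'   and `Gamma` commits.
#' @export
ecm_update_component <- function(component, ds, resp, model,
                                 control = list(), trace = FALSE) {
  ctrl <- default_control(control)
  two <- inherits(model, "two_sample_model")
  pairs <- if (two) CHAIN_TWO_SAMPLE else CHAIN_ONE_SAMPLE
  sm <- model_samples(model, ds)
  if (component %in% TOP_COMPONENTS) {
    rw <- resp$omega[, component]
    ss <- sm$s1
    if (two && length(sm$s2)) {
      rw <- c(rw, resp$nu[, component])
      ss <- c(ss, sm$s2)
    }
  } else {
    if (!two) stop("component ", component, " not part of a one-sample model")
    rw <- resp$nu[, component]
    ss <- sm$s2
  }
  modes <- vapply(model$theta, sn_mode, numeric(1))
  res <- update_one_component(component, rw, ss, model$theta[[component]],
                              model$theta, modes, pairs, ctrl, trace = trace)
  if (trace) res$trace else res$theta[[component]]
}

# ---------------------------------------------------------------------------
# KKT weight update

# Solve the stationarity + simplex + active-equality system for a given
# active set by damped Newton on log-weights (positivity is built in).
# A, B: responsibility sums for w and v. Residuals are scaled by the sample
# sizes so the convergence tolerance is size-independent.
solve_kkt_system <- function(A, B, v_phi, active, ctrl) {
  k <- length(active)
  n1 <- sum(A); n2 <- sum(B)
  A <- pmax(A, 1e-12 * n1)   # guard degenerate components
  B <- pmax(B, 1e-12 * n2)
  cw <- B_COEF_W[active, , drop = FALSE]
  cvp <- B_COEF_VP[active, , drop = FALSE]
  cst <- B_CONST[active] * v_phi
  sc <- 1 - v_phi
  # unknown vector: u_w (3), u_v (5) with w = exp(u_w), v = exp(u_v),
  # then gamma1/n1, gamma2/n2, eta/n1 (k)
  resid <- function(x) {
    w <- exp(x[1:3]); v <- exp(x[4:8])
    g1 <- x[9] * n1; g2 <- x[10] * n2
    eta <- if (k) x[10 + seq_len(k)] * n1 else numeric(0)
    c((A / w + g1 + if (k) drop(crossprod(cw, eta)) else 0) / n1,
      (B / v + g2 + if (k) sc * drop(crossprod(cvp, eta)) else 0) / n2,
      sum(w) - 1,
      sum(v) - 1,
      if (k) cst + drop(cw %*% w) + sc * drop(cvp %*% v) else numeric(0))
  }
  jac <- function(x) {
    w <- exp(x[1:3]); v <- exp(x[4:8])
    J <- matrix(0, 10 + k, 10 + k)
    J[1:3, 1:3] <- diag(-A / w / n1, 3)
    J[4:8, 4:8] <- diag(-B / v / n2, 5)
    J[1:3, 9] <- 1
    J[4:8, 10] <- 1
    if (k) {
      J[1:3, 10 + seq_len(k)] <- t(cw) * (n1 / n1)
      J[4:8, 10 + seq_len(k)] <- sc * t(cvp) * (n1 / n2)
      J[10 + seq_len(k), 1:3] <- cw %*% diag(w, 3)
      J[10 + seq_len(k), 4:8] <- sc * (cvp %*% diag(v, 5))
    }
    J[9, 1:3] <- w
    J[10, 4:8] <- v
    J
  }
  starts <- list(
    c(log(A / n1), log(B / n2), -1, -1, rep(0, k)),
    c(log(rep(1 / 3, 3)), log(rep(1 / 5, 5)), -1, -1, rep(0, k)))
  for (x in starts) {
    r <- resid(x)
    ok <- FALSE
    for (it in seq_len(ctrl$kkt_max_iter)) {
      if (max(abs(r)) < ctrl$kkt_tol) { ok <- TRUE; break }
      step <- tryCatch(solve(jac(x), -r), error = function(e) NULL)
      if (is.null(step)) break
      # cap the log-space step to keep exp() tame, then halve on
      # non-decreasing residual
      cap <- max(1, max(abs(step[1:8])) / 4)
      step <- step / cap
      t_damp <- 1
      improved <- FALSE
      while (t_damp >= 1e-10) {
        r_new <- resid(x + t_damp * step)
        if (all(is.finite(r_new)) && max(abs(r_new)) < max(abs(r))) {
          x <- x + t_damp * step; r <- r_new; improved <- TRUE; break
        }
        t_damp <- t_damp / 2
      }
      if (!improved) break
    }
    if (ok || max(abs(r)) < ctrl$kkt_tol) {
      w <- stats::setNames(exp(x[1:3]), TOP_COMPONENTS)
      v <- stats::setNames(exp(x[4:8]), ALL_COMPONENTS)
      eta <- stats::setNames(numeric(8), B_CONSTRAINT_NAMES)
      if (k) eta[active] <- x[10 + seq_len(k)] * n1
      return(list(w = w, v = v,
                  gamma = c(gamma1 = x[9] * n1, gamma2 = x[10] * n2),
                  eta = eta, residual = max(abs(resid(x)))))
    }
  }
  NULL
}

kkt_objective <- function(A, B, w, v) sum(A * log(w)) + sum(B * log(v))

#' Constrained mixing-weight update via KKT systems
#'
#' Maximizes the weight part of the Q-function,
#' `sum(A_X log w_X) + sum(B_Y log v_Y)` with `A`, `B` the responsibility
#' sums, subject to the simplex equalities and constraint set B. Follows a
#' greedy active-set schedule: first all inequality multipliers at zero
#' (responsibility averages); if the result violates set B, re-solve with
#' each violated constraint active singly, then pairs, and so on up to all
#' eight. Each candidate system is solved by damped Newton with an analytic
#' Jacobian; a solution is accepted when it is primal feasible (set B and
#' positivity) and dual feasible (non-negative inequality multipliers), and
#' the best accepted solution of the level is returned.
#'
#' @param A named responsibility sums over `C`, `J1`, `I1` (top scores).
#' @param B named responsibility sums over the five components (observed
#'   second scores).
#' @param v_phi missing-second-score proportion (constant of the dataset).
#' @param control list of control parameters.
#' @return A list with `w`, `v`, `gamma` (2 equality multipliers), `eta`
#'   (8 inequality multipliers, zero when inactive), `active_set`
#'   (character), `level` (number of active constraints used) and
#'   `residual` (stationarity residual).
#' @export
solve_weights_kkt <- function(A, B, v_phi, control = list()) {
  ctrl <- default_control(control)
  A <- A[TOP_COMPONENTS]; B <- B[ALL_COMPONENTS]
  stopifnot(all(A >= 0), all(B >= 0), v_phi >= 0, v_phi < 1)
  feas_tol <- 1e-9
  eta_tol <- 1e-8 * (sum(A) + sum(B))   # dual feasibility, scale-relative
  accept <- function(sol) {
    if (is.null(sol)) return(FALSE)
    if (any(sol$w <= 0) || any(sol$v <= 0)) return(FALSE)
    if (any(sol$eta < -eta_tol)) return(FALSE)
    all(weight_slack_B(sol$w, sol$v, v_phi) >= -feas_tol)
  }
  # Level 0: no active inequality constraint -- closed form.
  w0 <- A / sum(A)
  v0 <- B / sum(B)
  rep0 <- check_weights_B(w0, v0, v_phi, tol = feas_tol)
  if (rep0$satisfied) {
    return(list(w = w0, v = v0,
                gamma = c(gamma1 = -sum(A), gamma2 = -sum(B)),
                eta = stats::setNames(numeric(8), B_CONSTRAINT_NAMES),
                active_set = character(0), level = 0L, residual = 0))
  }
  violated <- rep0$violated
  for (k in 1:8) {
    cand_sets <- if (k <= 2L && length(violated) >= k) {
      utils::combn(violated, k, simplify = FALSE)
    } else {
      utils::combn(B_CONSTRAINT_NAMES, k, simplify = FALSE)
    }
    # prefer active sets containing the violated constraints
    n_viol <- vapply(cand_sets, function(s) sum(s %in% violated), numeric(1))
    cand_sets <- cand_sets[order(-n_viol)]
    best <- NULL; best_obj <- -Inf
    for (s in cand_sets) {
      sol <- solve_kkt_system(A, B, v_phi, s, ctrl)
      if (accept(sol)) {
        obj <- kkt_objective(A, B, sol$w, sol$v)
        if (obj > best_obj) {
          best <- c(sol, list(active_set = s, level = k))
          best_obj <- obj
        }
      }
    }
    if (!is.null(best)) return(best)
  }
  stop("solve_weights_kkt: no feasible stationary point at any active-set ",
       "level; responsibility sums A = ", paste(signif(A, 4), collapse = ", "),
       "; B = ", paste(signif(B, 4), collapse = ", "), "; v_phi = ", v_phi)
}

#' Number of distinct KKT stationarity systems
#'
#' Enumerates the subsets of the eight inequality-constraint multipliers
#' that the exhaustive (non-greedy) weight update would have to consider;
#' each subset yields a distinct system of stationarity equations.
#'
#' @param n_ineq number of inequality constraints (8 for constraint set B).
#' @return Integer count of distinct systems.
#' @export
kkt_system_count <- function(n_ineq = 8L) {
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n_ineq))
  nrow(unique(subsets))
}

# ---------------------------------------------------------------------------
# Binned-score representation

# Collapse a large score dataset to weighted bins: each sample is split
# into equal-width bins over its range, empty bins dropped, and each bin
# represented by the mean of its scores with the bin count as multiplicity.
# All ECM sums are weighted, so fitting binned scores maximizes the binned
# likelihood exactly; with thousands of bins the quantization is far below
# the statistical noise. The original missing-score proportion and top
# score moments are carried as attributes.
bin_scores <- function(ds, n_bins = 2000L) {
  stopifnot(inherits(ds, "score_dataset"), n_bins >= 10L)
  bin1 <- function(x) {
    br <- seq(min(x), max(x), length.out = n_bins + 1L)
    idx <- findInterval(x, br, rightmost.closed = TRUE)
    centers <- vapply(split(x, idx), mean, numeric(1))
    counts <- as.numeric(table(idx))
    list(x = unname(centers), n = counts)
  }
  b1 <- bin1(ds$s1)
  obs <- !is.na(ds$s2)
  b2 <- if (any(obs)) bin1(ds$s2[obs]) else list(x = numeric(0),
                                                 n = numeric(0))
  k <- max(length(b1$x), length(b2$x))
  pad <- function(v, fill, k) c(v, rep(fill, k - length(v)))
  out <- score_dataset(pad(b1$x, b1$x[length(b1$x)], k),
                       pad(b2$x, NA_real_, k), check_order = FALSE)
  attr(out, "wt1") <- pad(b1$n, 0, k)
  attr(out, "wt2") <- pad(b2$n, NA_real_, k)
  attr(out, "v_phi_fixed") <- compute_v_phi(ds)
  attr(out, "s1_moments") <- c(mean = mean(ds$s1), sd = stats::sd(ds$s1))
  out
}

# ---------------------------------------------------------------------------
# Initialization

#' Random initialization of the mixture model
#'
#' Draws one random starting point: a normal distribution is fitted to the
#' top scores (moments `mu`, `sigma`); component locations are five draws
#' from it, sorted in decreasing order and assigned to `C`, `J1`, `J2`,
#' `I1`, `I2`; scales are uniform on `[sigma/4, sigma]`; skewness
#' magnitudes are uniform on `[1/lambda0, lambda0]` with signs positive for
#' `C`, negative for `J2`, `I1`, `I2`, and `sign_J1` for `J1`. Draws
#' violating the density-dominance chain are discarded and resampled.
#' Initial weights are `w = (1/3, 1/3, 1/3)` and
#' `v = (0.001, 0.999/4, 0.999/4, 0.999/4, 0.999/4)`; the weight
#' constraints are not required to hold at initialization.
#'
#' @param ds a [score_dataset()] with at least 10 spectra.
#' @param lambda0 skewness range parameter, one of 1, 2, 5.
#' @param sign_J1 sign of the `J1` skewness, `+1` or `-1`.
#' @param max_tries resampling budget before giving up.
#' @param control list of control parameters.
#' @return A chain-feasible [two_sample_model()].
#' @export
init_params <- function(ds, lambda0 = 2, sign_J1 = 1, max_tries = 50000L,
                        control = list()) {
  init_pair(ds, lambda0, max_tries = max_tries, control = control)[[
    if (sign_J1 > 0) 1L else 2L]]
}

# Standardized SN mode offsets for a matrix of shape parameters, by
# vectorized bisection of the score equation z = |l| * mills(|l| z).
mode_offsets <- function(lam) {
  al <- abs(lam)
  lo <- array(0, dim = dim(al))
  hi <- array(1.1, dim = dim(al))
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    x <- al * mid
    hz <- -mid + al * exp(stats::dnorm(x, log = TRUE) -
                            stats::pnorm(x, log.p = TRUE))
    pos <- hz > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  sign(lam) * (lo + hi) / 2
}

# Row-wise SN log-density of a matrix of abscissae X (one parameter triple
# per row, recycled across columns).
ldsn_rows <- function(X, mu, sigma, lam) {
  z <- (X - mu) / sigma
  log(2) - log(sigma) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(lam * z, log.p = TRUE)
}

# Row-wise dominance screen for one (f, g) pair over many candidate draws:
# mode ordering plus positivity of log f - log g on quadratically spaced
# grids right of mode(f) and (negated) left of mode(g).
rows_dominate <- function(muF, sigF, lamF, muG, sigG, lamG,
                          modeF, modeG, u2, window = 12) {
  ok <- modeF > modeG
  scale <- pmax(sigF, sigG)
  Xr <- modeF + (window * scale) %o% u2
  dr <- ldsn_rows(Xr, muF, sigF, lamF) - ldsn_rows(Xr, muG, sigG, lamG)
  ok <- ok & rowSums(dr <= 0) == 0L
  Xl <- modeG - (window * scale) %o% u2
  dl <- ldsn_rows(Xl, muG, sigG, lamG) - ldsn_rows(Xl, muF, sigF, lamF)
  ok & rowSums(dl <= 0) == 0L
}

# The two sign variants of one initialization round (identical parameter
# draws except the sign of lambda_J1), each resampled until it satisfies
# the dominance chain. Feasibility is screened per sign: requiring one
# draw to be feasible under both signs simultaneously makes acceptance
# prohibitively rare for some lambda0. Draws are screened in vectorized
# batches; accepted draws are re-verified at full resolution.
init_pair <- function(ds, lambda0, max_tries = 50000L, control = list()) {
  ctrl <- default_control(control)
  stopifnot(inherits(ds, "score_dataset"), nrow(ds) >= 10L,
            lambda0 >= 1)
  mo <- attr(ds, "s1_moments")
  if (is.null(mo)) mo <- c(mean = mean(ds$s1), sd = stats::sd(ds$s1))
  mu0 <- mo[["mean"]]; sd0 <- mo[["sd"]]
  v_phi <- compute_v_phi(ds)
  w0 <- stats::setNames(rep(1 / 3, 3), TOP_COMPONENTS)
  v0 <- stats::setNames(c(0.001, rep(0.999 / 4, 4)), ALL_COMPONENTS)
  u2 <- seq(0, 1, length.out = 48L)^2
  batch <- 512L
  # screening order: the strongly rejecting negative-negative pairs first
  pair_idx <- rbind(c(3L, 4L), c(4L, 5L), c(2L, 3L), c(1L, 2L))
  found <- list(NULL, NULL)
  drawn <- 0L
  while (drawn < max_tries) {
    B <- min(batch, max_tries - drawn)
    drawn <- drawn + B
    locs <- matrix(stats::rnorm(5L * B, mu0, sd0), B, 5L, byrow = TRUE)
    locs <- t(apply(locs, 1L, sort, decreasing = TRUE))
    sigmas <- matrix(stats::runif(5L * B, sd0 / 4, sd0), B, 5L,
                     byrow = TRUE)
    abs_l <- matrix(stats::runif(5L * B, 1 / lambda0, lambda0), B, 5L,
                    byrow = TRUE)
    lam_signs <- list(c(1, 1, -1, -1, -1), c(1, -1, -1, -1, -1))
    lam_by_sign <- lapply(lam_signs, function(s)
      sweep(abs_l, 2L, s, `*`))
    for (s in 1:2) {
      if (!is.null(found[[s]])) next
      lam <- lam_by_sign[[s]]
      ok <- rep(TRUE, B)
      modes <- locs + mode_offsets(lam) * sigmas
      for (k in seq_len(nrow(pair_idx))) {
        i <- pair_idx[k, 1L]; j <- pair_idx[k, 2L]
        live <- which(ok)
        if (!length(live)) break
        ok[live] <- rows_dominate(
          locs[live, i], sigmas[live, i], lam[live, i],
          locs[live, j], sigmas[live, j], lam[live, j],
          modes[live, i], modes[live, j], u2)
      }
      for (row in which(ok)) {
        theta <- stats::setNames(lapply(1:5, function(i)
          sn_params(locs[row, i], sigmas[row, i], lam[row, i])),
          ALL_COMPONENTS)
        if (check_chain(theta, pairs = CHAIN_TWO_SAMPLE,
                        n_grid = max(ctrl$n_grid, 512L))$ok) {
          found[[s]] <- two_sample_model(theta, w0, v0, v_phi)
          break
        }
      }
    }
    if (!is.null(found[[1L]]) && !is.null(found[[2L]])) return(found)
  }
  stop("init_pair: could not draw chain-feasible initial parameters in ",
       max_tries, " attempts")
}

init_one_sample <- function(ds, lambda0, sign_J1, max_tries = 50000L,
                            control = list()) {
  ctrl <- default_control(control)
  stopifnot(inherits(ds, "score_dataset"), nrow(ds) >= 10L)
  mo <- attr(ds, "s1_moments")
  if (is.null(mo)) mo <- c(mean = mean(ds$s1), sd = stats::sd(ds$s1))
  mu0 <- mo[["mean"]]; sd0 <- mo[["sd"]]
  w0 <- stats::setNames(rep(1 / 3, 3), TOP_COMPONENTS)
  u2 <- seq(0, 1, length.out = 96L)^2
  batch <- 512L
  pair_idx <- rbind(c(1L, 2L), c(2L, 3L))
  signs <- c(1, sign_J1, -1)
  drawn <- 0L
  while (drawn < max_tries) {
    B <- min(batch, max_tries - drawn)
    drawn <- drawn + B
    locs <- matrix(stats::rnorm(3L * B, mu0, sd0), B, 3L, byrow = TRUE)
    locs <- t(apply(locs, 1L, sort, decreasing = TRUE))
    sigmas <- matrix(stats::runif(3L * B, sd0 / 4, sd0), B, 3L,
                     byrow = TRUE)
    lam <- sweep(matrix(stats::runif(3L * B, 1 / lambda0, lambda0),
                        B, 3L, byrow = TRUE), 2L, signs, `*`)
    modes <- locs + mode_offsets(lam) * sigmas
    ok <- rep(TRUE, B)
    for (k in seq_len(nrow(pair_idx))) {
      i <- pair_idx[k, 1L]; j <- pair_idx[k, 2L]
      live <- which(ok)
      if (!length(live)) break
      ok[live] <- rows_dominate(
        locs[live, i], sigmas[live, i], lam[live, i],
        locs[live, j], sigmas[live, j], lam[live, j],
        modes[live, i], modes[live, j], u2)
    }
    for (row in which(ok)) {
      theta <- stats::setNames(lapply(1:3, function(i)
        sn_params(locs[row, i], sigmas[row, i], lam[row, i])),
        TOP_COMPONENTS)
      if (check_chain(theta, pairs = CHAIN_ONE_SAMPLE,
                      n_grid = max(ctrl$n_grid, 512L))$ok)
        return(one_sample_model(theta, w0))
    }
  }
  stop("init_one_sample: could not draw chain-feasible initial parameters")
}

#' Number of random initializations
#'
#' The restart structure of the fitting procedure: each sampling round
#' yields, for every value of `lambda0`, two initializations differing only
#' in the sign of the `J1` skewness.
#'
#' @param rounds number of sampling rounds.
#' @param lambda0 set of skewness range parameters.
#' @param signs_J1 number of `J1` skewness signs.
#' @return Integer number of initializations (240 at the defaults).
#' @export
n_initializations <- function(rounds = 40L, lambda0 = c(1, 2, 5),
                              signs_J1 = 2L) {
  as.integer(rounds) * length(lambda0) * as.integer(signs_J1)
}

# ---------------------------------------------------------------------------
# ECM driver

# One full ECM iteration; returns updated model plus bookkeeping.
ecm_step_internal <- function(model, ds, ctrl) {
  two <- inherits(model, "two_sample_model")
  pairs <- if (two) CHAIN_TWO_SAMPLE else CHAIN_ONE_SAMPLE
  comps <- if (two) ALL_COMPONENTS else TOP_COMPONENTS
  sm <- model_samples(model, ds)
  # E-step; the same pass gives the incoming model's log-likelihood
  e1 <- estep_sample(model$theta, TOP_COMPONENTS, sm$s1, model$w, sm$w1)
  resp <- list(omega = e1$resp)
  ll_in <- e1$loglik
  if (two && length(sm$s2)) {
    e2 <- estep_sample(model$theta, ALL_COMPONENTS, sm$s2, model$v, sm$w2)
    resp$nu <- e2$resp
    ll_in <- ll_in + e2$loglik
  } else if (two) {
    resp$nu <- matrix(numeric(0), 0L, length(ALL_COMPONENTS),
                      dimnames = list(NULL, ALL_COMPONENTS))
  }
  theta_bar <- model$theta
  theta <- model$theta
  modes <- vapply(theta, sn_mode, numeric(1))
  for (nm in comps) {
    if (nm %in% TOP_COMPONENTS) {
      rw <- resp$omega[, nm] * sm$w1; ss <- sm$s1
      if (two && length(sm$s2)) {
        rw <- c(rw, resp$nu[, nm] * sm$w2); ss <- c(ss, sm$s2)
      }
    } else {
      rw <- resp$nu[, nm] * sm$w2; ss <- sm$s2
    }
    res <- update_one_component(nm, rw, ss, theta_bar[[nm]], theta, modes,
                                pairs, ctrl)
    theta <- res$theta; modes <- res$modes
  }
  max_active <- 0L
  if (two) {
    A <- colSums(resp$omega * sm$w1)
    if (length(sm$s2)) {
      B <- colSums(resp$nu * sm$w2)
      sol <- solve_weights_kkt(A, B, model$v_phi, control = ctrl)
      w <- sol$w; v <- sol$v
      max_active <- sol$level
    } else {
      w <- A / sum(A); v <- model$v
    }
    w <- pmax(w, ctrl$weight_floor); w <- w / sum(w)
    v <- pmax(v, ctrl$weight_floor); v <- v / sum(v)
    model_new <- two_sample_model(theta, w, v, model$v_phi)
  } else {
    A <- colSums(resp$omega * sm$w1)
    w <- pmax(A / sum(A), ctrl$weight_floor); w <- w / sum(w)
    model_new <- one_sample_model(theta, w)
  }
  list(model = model_new, max_active = max_active, loglik_in = ll_in)
}

#' One constrained ECM iteration
#'
#' Runs a single expectation step followed by all conditional-maximization
#' updates (component parameters in chain order, then mixing weights).
#' Mainly useful for step-level testing and diagnostics; [fit_xl_mixture()]
#' iterates this to convergence.
#'
#' @param model current [two_sample_model()] or [one_sample_model()].
#' @param ds a [score_dataset()].
#' @param control list of control parameters.
#' @return A list with the updated `model` and `max_active`, the number of
#'   active inequality constraints used by the weight update.
#' @export
ecm_step <- function(model, ds, control = list()) {
  ecm_step_internal(model, ds, default_control(control))
}

run_ecm <- function(model, ds, tol, max_iter, ctrl) {
  # Each E-step yields the incoming model's log-likelihood for free, so the
  # convergence check compares successive incoming values (one-step lag).
  trace <- numeric(0)
  max_active <- 0L
  converged <- FALSE
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    st <- ecm_step_internal(model, ds, ctrl)
    model <- st$model
    max_active <- max(max_active, st$max_active)
    trace <- c(trace, st$loglik_in)
    if (is.finite(ll) &&
        abs(st$loglik_in - ll) / (abs(st$loglik_in) + 1) < tol) {
      converged <- TRUE
      ll <- st$loglik_in
      break
    }
    ll <- st$loglik_in
  }
  ll_final <- loglik(model, ds)
  list(model = model, loglik = ll_final,
       loglik_trace = c(trace, ll_final),
       iterations = length(trace), converged = converged,
       max_active = max_active)
}

#' Fit the constrained skew-normal mixture by multi-restart ECM
#'
#' Fits the two-sample (default) or one-sample skew-normal mixture to a
#' paired score dataset by the constrained ECM algorithm, from multiple
#' random initializations, returning the restart attaining the maximum
#' observed-data log-likelihood. The default restart structure is 40
#' sampling rounds, each giving six initializations
#' (`lambda0` in {1, 2, 5} times two signs of the `J1` skewness), i.e. 240
#' restarts. The run is deterministic given `seed`.
#'
#' @param ds a [score_dataset()].
#' @param model `"two-sample"` or `"one-sample"`.
#' @param n_restarts number of restarts (rounded up to full rounds of 6).
#' @param seed integer seed driving all initialization randomness.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum ECM iterations per restart.
#' @param init_models optional list of models used as extra (deterministic)
#'   starting points, e.g. a previous fit for warm-started refits.
#' @param short_iter when positive, restarts are first run for this many
#'   iterations only and the `top_k` by log-likelihood are continued to
#'   `max_iter` (a short-run/long-run schedule; 0 disables it and runs
#'   every restart to convergence).
#' @param top_k number of short-run leaders continued to full length.
#' @param bin_n when positive, large datasets are collapsed to this many
#'   weighted score bins per sample before fitting (exact weighted ECM on
#'   the binned likelihood; quantization far below statistical noise at
#'   the default resolution). 0 fits the raw scores.
#' @param control list of control parameters.
#' @return An object of class `"xl_fit"`: the best `model`, its `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, a `restarts` summary data
#'   frame, the maximum number of simultaneously active weight constraints
#'   (`max_active`) and the `seed`.
#' @export
fit_xl_mixture <- function(ds, model = c("two-sample", "one-sample"),
                           n_restarts = 240L, seed = 1L, tol = 1e-8,
                           max_iter = 1000L, init_models = NULL,
                           short_iter = 0L, top_k = 6L, bin_n = 0L,
                           control = list()) {
  model <- match.arg(model)
  ctrl <- default_control(control)
  stopifnot(inherits(ds, "score_dataset"), nrow(ds) >= 1L)
  if (bin_n > 0L && nrow(ds) > 2L * bin_n) ds <- bin_scores(ds, bin_n)
  two <- model == "two-sample"
  lambda0_set <- c(1, 2, 5)
  rounds <- ceiling(max(n_restarts - length(init_models), 0) /
                      (2 * length(lambda0_set)))
  starts <- list()
  for (r in seq_len(rounds)) {
    for (li in seq_along(lambda0_set)) {
      sd_rl <- child_seed(seed, (r - 1L) * length(lambda0_set) + li)
      pair <- with_seed(sd_rl, {
        if (two) init_pair(ds, lambda0_set[li], control = ctrl)
        else list(init_one_sample(ds, lambda0_set[li], +1, control = ctrl),
                  init_one_sample(ds, lambda0_set[li], -1, control = ctrl))
      })
      starts <- c(starts, pair)
    }
  }
  starts <- c(init_models, starts)
  if (length(starts) > n_restarts) starts <- starts[seq_len(n_restarts)]
  continue <- rep(TRUE, length(starts))
  if (short_iter > 0L && length(starts) > top_k) {
    # short-run screening: a brief ECM burst per restart, keeping only the
    # leaders for the full run
    short_ll <- rep(NA_real_, length(starts))
    for (i in seq_along(starts)) {
      res <- tryCatch(run_ecm(starts[[i]], ds, tol, short_iter, ctrl),
                      error = function(e) NULL)
      if (!is.null(res)) {
        starts[[i]] <- res$model
        short_ll[i] <- res$loglik
      }
    }
    keep <- order(-short_ll)[seq_len(min(top_k, sum(!is.na(short_ll))))]
    continue <- seq_along(starts) %in% keep
  }
  results <- vector("list", length(starts))
  summary_rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    res <- if (!continue[i]) {
      simpleError("dropped after short-run screening")
    } else {
      tryCatch(run_ecm(starts[[i]], ds, tol, max_iter, ctrl),
               error = function(e) e)
    }
    if (inherits(res, "error")) {
      summary_rows[[i]] <- data.frame(restart = i, loglik = NA_real_,
                                      iterations = NA_integer_,
                                      converged = FALSE, max_active = NA,
                                      error = conditionMessage(res))
    } else {
      results[[i]] <- res
      summary_rows[[i]] <- data.frame(restart = i, loglik = res$loglik,
                                      iterations = res$iterations,
                                      converged = res$converged,
                                      max_active = res$max_active,
                                      error = NA_character_)
    }
  }
  summary_df <- do.call(rbind, summary_rows)
  ok <- which(!is.na(summary_df$loglik))
  if (!length(ok))
    stop("fit_xl_mixture: all restarts failed; first error: ",
         summary_df$error[1L])
  best <- ok[which.max(summary_df$loglik[ok])]
  res <- results[[best]]
  structure(list(model = res$model, loglik = res$loglik,
                 loglik_trace = res$loglik_trace,
                 iterations = res$iterations, converged = res$converged,
                 restarts = summary_df, best_restart = best,
                 max_active = max(summary_df$max_active, na.rm = TRUE),
                 seed = seed, kind = model),
            class = "xl_fit")
}

#' Fit the one-sample (top-score only) mixture
#'
#' Convenience wrapper around [fit_xl_mixture()] with
#' `model = "one-sample"`: a three-component mixture for the top score with
#' the dominance chain `C > J1 > I1` enforced and an unconstrained weight
#' update (the latent-structure weight constraints do not apply without the
#' second sample).
#'
#' @inheritParams fit_xl_mixture
#' @return An `"xl_fit"` object over a [one_sample_model()].
#' @export
fit_one_sample <- function(ds, n_restarts = 240L, seed = 1L, tol = 1e-8,
                           max_iter = 1000L, bin_n = 0L, control = list()) {
  fit_xl_mixture(ds, model = "one-sample", n_restarts = n_restarts,
                 seed = seed, tol = tol, max_iter = max_iter, bin_n = bin_n,
                 control = control)
}

#' @export
print.xl_fit <- function(x, ...) {
  cat(sprintf("Constrained ECM fit (%s), %d restart(s)\n",
              x$kind, nrow(x$restarts)))
  cat(sprintf("  best log-likelihood: %.4f (restart %d, %d iterations, %s)\n",
              x$loglik, x$best_restart, x$iterations,
              if (x$converged) "converged" else "iteration limit"))
  cat(sprintf("  max active weight constraints: %d\n", x$max_active))
  print(x$model)
  invisible(x)
}
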