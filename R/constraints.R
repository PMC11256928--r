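# Latent-structure constraints on mixing weights and component densities.
#
# The top and second scores of one spectrum cannot come from the same latent
# match, and the runner-up components J2/I2 can appear in the second score
# only when the top score came from J1/I1. These facts bound each mixing
# weight by sums of others (set A). Because second scores are missing
# preferentially in the left tail of the top-score distribution, set A is
# invalid under missingness; set B rescales the second-score weights by
# (1 - v_phi) and adds v_phi to the upper bounds, which is valid regardless
# of how the missingness depends on the scores.

B_CONSTRAINT_NAMES <- paste0("b", 1:8)

# Signed slack of each set-B inequality (>= 0 means satisfied), in the fixed
# order b1..b8: three upper bounds on w, then five upper bounds on v'.
weight_slack_B <- function(w, v, v_phi) {
  vp <- (1 - v_phi) * v
  c(b1 = vp[["J1"]] + vp[["I1"]] + v_phi - w[["C"]],
    b2 = vp[["C"]] + vp[["J2"]] + vp[["I1"]] + v_phi - w[["J1"]],
    b3 = vp[["C"]] + vp[["J1"]] + vp[["I2"]] + v_phi - w[["I1"]],
    b4 = w[["J1"]] + w[["I1"]] - vp[["C"]],
    b5 = w[["C"]] + w[["I1"]] - vp[["J1"]],
    b6 = w[["C"]] + w[["J1"]] - vp[["I1"]],
    b7 = w[["J1"]] - vp[["J2"]],
    b8 = w[["I1"]] - vp[["I2"]])
}

#' Check the mixing-weight constraint set B
#'
#' Evaluates the eight inequality constraints relating the top-score weights
#' `w` and the second-score weights `v`, with the second-score weights scaled
#' as `v' = (1 - v_phi) * v` and the missing-score proportion `v_phi` added
#' to the upper bounds. With `v_phi = 0` this reduces exactly to constraint
#' set A.
#'
#' @param w named weights over `C`, `J1`, `I1`.
#' @param v named weights over `C`, `J1`, `J2`, `I1`, `I2`.
#' @param v_phi proportion of spectra with missing second scores.
#' @param tol slack tolerance; inequalities violated by less than `tol` are
#'   treated as satisfied to avoid chatter at equality.
#' @return A list with `satisfied` (logical), `violated` (character vector
#'   of constraint names among `b1..b8`) and `slack` (named numeric).
#' @export
check_weights_B <- function(w, v, v_phi, tol = 1e-12) {
  stopifnot(v_phi >= 0, v_phi <= 1)
  sl <- weight_slack_B(w, v, v_phi)
  viol <- names(sl)[sl < -tol]
  list(satisfied = length(viol) == 0L, violated = viol, slack = sl)
}

#' Check the mixing-weight constraint set A
#'
#' The no-missingness form of the weight constraints; equal to
#' [check_weights_B()] at `v_phi = 0`. Kept for reference and testing; the
#' fitting algorithm always uses set B.
#'
#' @inheritParams check_weights_B
#' @return As [check_weights_B()].
#' @export
check_weights_A <- function(w, v, tol = 1e-12) {
  check_weights_B(w, v, v_phi = 0, tol = tol)
}

# Far-tail log-density decay coefficients of an SN component: the leading
# quadratic term is -(x-mu)^2/(2 sigma^2), with an extra -lambda^2 (x-mu)^2 /
# (2 sigma^2) on the side penalized by the skewness (the right tail when
# lambda < 0, the left tail when lambda > 0).
tail_coef <- function(p) {
  c(right = (1 + max(0, -p$lambda)^2) / p$sigma^2,
    left  = (1 + max(0,  p$lambda)^2) / p$sigma^2)
}

# Grid with quadratic spacing: dense near `from`, sparse towards `to`
# (dominance violations concentrate near the modes; far-field minima of the
# log-density difference are broad and survive coarse sampling + polishing).
dom_grid <- function(from, to, n_grid) {
  u <- seq(0, 1, length.out = n_grid)
  from + (to - from) * u^2
}

#' Test the density-dominance partial order f > g
#'
#' `f` dominates `g` when (i) `mode(f) > mode(g)`, (ii) `f(x) > g(x)` for
#' `x > mode(f)`, and (iii) `g(x) > f(x)` for `x < mode(g)`. Conditions
#' (ii) and (iii) are checked on a dense grid spanning `window` times the
#' larger scale beyond each mode, with interior minima of the log-density
#' difference polished by bounded minimization. By default the check stops
#' at the window edge, where both densities are below `exp(-window^2/2)`
#' (about 5e-32 of their modal values at the default window) of their modal
#' values: dominance is enforced wherever the densities are numerically
#' meaningful. With `tails = "asymptotic"` the unbounded far tails are
#' additionally compared through the leading quadratic decay coefficients
#' of the SN log-density (`-(1 + max(0, -lambda)^2) (x-mu)^2 / (2 sigma^2)`
#' on the right and symmetrically on the left), giving the strict
#' mathematical order; that variant rejects nearly every random scale/shape
#' draw and is provided for analysis rather than fitting.
#'
#' @param f,g [sn_params()] objects (candidate dominating and dominated).
#' @param mode_f,mode_g optional precomputed modes (see [sn_mode()]).
#' @param n_grid grid points per side.
#' @param tol equality tolerance on modes and tail coefficients.
#' @param window half-width of the checked region, in units of the larger
#'   scale.
#' @param tails `"window"` (default) or `"asymptotic"`.
#' @return `TRUE` iff all conditions hold (numerically).
#' @export
check_dominance <- function(f, g, mode_f = NULL, mode_g = NULL,
                            n_grid = 512L, tol = 1e-12, window = 12,
                            tails = c("window", "asymptotic")) {
  stopifnot(inherits(f, "sn_params"), inherits(g, "sn_params"))
  tails <- match.arg(tails)
  if (tails == "asymptotic") {
    # Pure-arithmetic far-tail conditions, tested before the (costlier)
    # numeric mode search: f must not decay faster than g on the right,
    # g must not decay faster than f on the left.
    tf <- tail_coef(f); tg <- tail_coef(g)
    if (tf[["right"]] > tg[["right"]] + tol) return(FALSE)
    if (tg[["left"]] > tf[["left"]] + tol) return(FALSE)
  }
  if (is.null(mode_f)) mode_f <- sn_mode(f)
  if (is.null(mode_g)) mode_g <- sn_mode(g)
  scale <- max(f$sigma, g$sigma)
  if (!(mode_f - mode_g > tol * max(1, scale))) return(FALSE)

  # Grid scan of log f - log g over both windows (quadratic spacing, dense
  # near the modes) with golden-section polishing of interior local minima;
  # compiled kernel.
  cpp_dominance_grid_ok(f$mu, f$sigma, f$lambda, g$mu, g$sigma, g$lambda,
                        mode_f, mode_g, as.integer(n_grid), window)
}

#' Check the component density-dominance chain
#'
#' Verifies the enforced pairwise dominance relations: for the two-sample
#' model the chain `C > J1 > J2 > I1 > I2` (four adjacent pairs); for the
#' one-sample model `C > J1 > I1`.
#'
#' @param theta named list of [sn_params()].
#' @param pairs list of `c(upper, lower)` component-name pairs; defaults to
#'   the five-component chain when `theta` has five entries, else the
#'   three-component chain.
#' @param modes optional named numeric of precomputed modes.
#' @param n_grid grid points per dominance check.
#' @return A list with `ok` (logical) and `violated` (the first violated
#'   pair as `c(upper, lower)`, or `NULL`).
#' @export
check_chain <- function(theta, pairs = NULL, modes = NULL, n_grid = 512L) {
  if (is.null(pairs)) {
    pairs <- if (all(ALL_COMPONENTS %in% names(theta))) CHAIN_TWO_SAMPLE
             else CHAIN_ONE_SAMPLE
  }
  for (pr in pairs) {
    # modes are computed lazily inside check_dominance when not supplied,
    # so draws failing the cheap tail screens never pay for a mode search
    if (!check_dominance(theta[[pr[1L]]], theta[[pr[2L]]],
                         mode_f = if (!is.null(modes)) modes[[pr[1L]]],
                         mode_g = if (!is.null(modes)) modes[[pr[2L]]],
                         n_grid = n_grid))
      return(list(ok = FALSE, violated = pr))
  }
  list(ok = TRUE, violated = NULL)
}

# Replace one parameter of one component (alternate parametrization for
# Delta/Gamma) and return the full canonical parameter list.
set_component_param <- function(theta, component, param, value) {
  p <- theta[[component]]
  if (param == "mu") {
    theta[[component]] <- sn_params(value, p$sigma, p$lambda)
  } else {
    a <- to_alternate(p)
    a[[param]] <- value
    if (a$Gamma <= 0) stop("'Gamma' must stay positive")
    theta[[component]] <- from_alternate(a)
  }
  theta
}

# Pairs of the chain that involve a given component.
pairs_involving <- function(pairs, component) {
  Filter(function(pr) component %in% pr, pairs)
}

#' Repair an infeasible component-parameter update by binary search
#'
#' When a candidate update of one component parameter (`mu`, `Delta` or
#' `Gamma`) breaks a pairwise dominance constraint, searches the line
#' segment between the current (feasible) value and the candidate for the
#' feasible point closest to the candidate. The candidate is returned
#' unchanged when it is already feasible. Because the Q-function is concave
#' along each coordinate, the returned point never decreases it.
#'
#' @param component component name.
#' @param param one of `"mu"`, `"Delta"`, `"Gamma"`.
#' @param old_value current value (must be feasible in `theta_context`).
#' @param candidate_value proposed value.
#' @param theta_context named list of [sn_params()] holding all components
#'   at their current values (with `component` at `old_value`).
#' @param pairs dominance pairs to enforce (defaults as in [check_chain()]).
#' @param n_iter number of bisection steps.
#' @param n_grid grid points per dominance check.
#' @return The repaired (feasible) parameter value.
#' @export
binary_search_repair <- function(component, param, old_value, candidate_value,
                                 theta_context, pairs = NULL, n_iter = 60L,
                                 n_grid = 512L) {
  stopifnot(param %in% c("mu", "Delta", "Gamma"))
  if (is.null(pairs)) {
    pairs <- if (all(ALL_COMPONENTS %in% names(theta_context)))
      CHAIN_TWO_SAMPLE else CHAIN_ONE_SAMPLE
  }
  involved <- pairs_involving(pairs, component)
  feasible_at <- function(value) {
    th <- tryCatch(
      set_component_param(theta_context, component, param, value),
      error = function(e) NULL)
    if (is.null(th)) return(FALSE)
    check_chain(th, pairs = involved, n_grid = n_grid)$ok
  }
  if (!feasible_at(old_value))
    stop("binary_search_repair: current value is not feasible for ",
         component, "/", param)
  if (feasible_at(candidate_value)) return(candidate_value)
  lo <- 0; hi <- 1   # fraction of the way from old to candidate
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    if (feasible_at(old_value + mid * (candidate_value - old_value)))
      lo <- mid
    else
      hi <- mid
  }
  old_value + lo * (candidate_value - old_value)
}
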