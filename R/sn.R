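#' Skew-normal component parameters
#'
#' Constructs the canonical parametrization of a skew-normal (SN) score
#' component: location `mu`, scale `sigma` (> 0) and shape `lambda`. The SN
#' family generalizes the normal with a shape parameter controlling skewness:
#' right-skewed for `lambda > 0`, left-skewed for `lambda < 0`, exactly
#' normal at `lambda = 0`.
#'
#' @param mu location, in score units.
#' @param sigma scale, in score units; must be positive.
#' @param lambda shape (dimensionless).
#' @return An object of class `"sn_params"`: a list with elements
#'   `mu`, `sigma`, `lambda`.
#' @seealso [sn_alt_params()] for the alternate parametrization used by the
#'   ECM updates.
#' @examples
#' p <- sn_params(mu = 20, sigma = 5, lambda = -1.5)
#' dsn(20, p)
#' @export
sn_params <- function(mu, sigma, lambda) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (sigma <= 0) stop("'sigma' must be positive")
  structure(list(mu = mu, sigma = sigma, lambda = lambda),
            class = "sn_params")
}

#' @export
print.sn_params <- function(x, ...) {
  cat(sprintf("SN(mu = %.6g, sigma = %.6g, lambda = %.6g)\n",
              x$mu, x$sigma, x$lambda))
  invisible(x)
}

#' Alternate skew-normal parametrization
#'
#' The alternate parametrization `(mu, Delta, Gamma)` arises from the
#' stochastic representation `S = mu + Delta*T + sqrt(Gamma)*U` with
#' `T ~ TN+(0,1)` (standard normal truncated below 0) and `U ~ N(0,1)`.
#' It is related to the canonical form through `delta = lambda/sqrt(1+lambda^2)`,
#' `Delta = sigma*delta` and `Gamma = sigma^2 - Delta^2`.
#'
#' @param mu location (score units).
#' @param Delta signed scale-skew product (score units).
#' @param Gamma residual variance (score units squared); must be positive.
#' @return An object of class `"sn_alt_params"`.
#' @export
sn_alt_params <- function(mu, Delta, Gamma) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(Delta), length(Delta) == 1L, is.finite(Delta),
            is.numeric(Gamma), length(Gamma) == 1L, is.finite(Gamma))
  if (Gamma <= 0) stop("'Gamma' must be positive")
  structure(list(mu = mu, Delta = Delta, Gamma = Gamma),
            class = "sn_alt_params")
}

#' Convert canonical SN parameters to the alternate form
#'
#' @param p an [sn_params()] object.
#' @return An [sn_alt_params()] object with `Delta = sigma*delta` and
#'   `Gamma = sigma^2 - Delta^2`, where `delta = lambda/sqrt(1+lambda^2)`.
#' @export
to_alternate <- function(p) {
  stopifnot(inherits(p, "sn_params"))
  delta <- p$lambda / sqrt(1 + p$lambda^2)
  Delta <- p$sigma * delta
  Gamma <- p$sigma^2 - Delta^2
  sn_alt_params(p$mu, Delta, Gamma)
}

#' Convert alternate SN parameters back to canonical form
#'
#' @param a an [sn_alt_params()] object.
#' @return An [sn_params()] object; `sign(lambda)` equals `sign(Delta)`.
#' @export
from_alternate <- function(a) {
  stopifnot(inherits(a, "sn_alt_params"))
  lambda <- sign(a$Delta) * sqrt(a$Delta^2 / a$Gamma)
  sigma <- sqrt(a$Gamma + a$Delta^2)
  sn_params(a$mu, sigma, lambda)
}

#' Owen's T function
#'
#' Computes `T(h, a) = (2*pi)^(-1) * integral_0^a exp(-h^2(1+t^2)/2)/(1+t^2) dt`,
#' the ingredient of the skew-normal CDF. Arguments are reduced to
#' `|a| <= 1` through the symmetry `T(h,-a) = -T(h,a)` and the reciprocal
#' relation `T(h,a) = (Phi(h)+Phi(ah))/2 - Phi(h)Phi(ah) - T(ah, 1/a)`;
#' the remaining integral is evaluated adaptively.
#'
#' @param h numeric vector.
#' @param a numeric vector (recycled against `h`).
#' @return Numeric vector of the same length as `h` after recycling.
#' @export
owens_t <- function(h, a) {
  n <- max(length(h), length(a))
  h <- abs(rep_len(as.numeric(h), n))     # T(h, a) = T(-h, a)
  a <- rep_len(as.numeric(a), n)
  sgn <- sign(a)                          # T(h, -a) = -T(h, a)
  a <- abs(a)
  out <- numeric(n)
  big <- a > 1
  if (any(big)) {
    # reciprocal reduction keeps the integration interval within [0, 1]
    hb <- h[big]; ab <- a[big]
    out[big] <- 0.5 * (stats::pnorm(hb) + stats::pnorm(ab * hb)) -
      stats::pnorm(hb) * stats::pnorm(ab * hb) -
      owens_t_core(ab * hb, 1 / ab)
  }
  out[!big] <- owens_t_core(h[!big], a[!big])
  sgn * out
}

# Gauss-Legendre nodes/weights on [0, 1] by Golub-Welsch.
gl_nodes_01 <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}

.owens_env <- new.env(parent = emptyenv())

# Composite quadrature grid on [0, 1]: panels refined geometrically towards
# zero so the Gaussian factor exp(-h^2 t^2 / 2) is resolved for any h, with
# 12-point Gauss-Legendre inside each panel.
owens_grid <- function() {
  if (is.null(.owens_env$nodes)) {
    gl <- gl_nodes_01(12L)
    edges <- c(0, 2^seq(-10, 0))
    nodes <- numeric(0); weights <- numeric(0)
    for (i in seq_len(length(edges) - 1L)) {
      wdt <- edges[i + 1L] - edges[i]
      nodes <- c(nodes, edges[i] + wdt * gl$x)
      weights <- c(weights, wdt * gl$w)
    }
    .owens_env$nodes <- nodes
    .owens_env$weights <- weights
  }
  .owens_env
}

# T(h, a) for h >= 0, 0 <= a <= 1, by vectorized composite quadrature of
# the defining integral (1/2pi) \int_0^a exp(-h^2 (1+t^2)/2) / (1+t^2) dt.
owens_t_core <- function(h, a) {
  n <- length(h)
  if (!n) return(numeric(0))
  g <- owens_grid()
  out <- numeric(n)
  chunk <- 4096L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    tt <- outer(a[idx], g$nodes)              # t = a * u
    hh <- h[idx]
    f <- exp(-0.5 * hh^2 * (1 + tt^2)) / (1 + tt^2)
    out[idx] <- a[idx] * drop(f %*% g$weights) / (2 * pi)
  }
  out
}

norm_params <- function(x, p, mu, sigma, lambda) {
  if (!is.null(p)) {
    stopifnot(inherits(p, "sn_params"))
    list(mu = p$mu, sigma = p$sigma, lambda = p$lambda)
  } else {
    list(mu = mu, sigma = sigma, lambda = lambda)
  }
}

#' Skew-normal density
#'
#' `f(s) = (2/sigma) * phi((s-mu)/sigma) * Phi(lambda*(s-mu)/sigma)`.
#' Computed in log space so far-tail values underflow gracefully.
#'
#' @param x numeric vector of scores.
#' @param p an [sn_params()] object (or supply `mu`, `sigma`, `lambda`).
#' @param mu,sigma,lambda scalar parameters, used when `p` is `NULL`.
#' @param log logical; return the log-density.
#' @return Numeric vector of densities (per score unit).
#' @export
dsn <- function(x, p = NULL, mu = 0, sigma = 1, lambda = 0, log = FALSE) {
  pp <- norm_params(x, p, mu, sigma, lambda)
  z <- (x - pp$mu) / pp$sigma
  lf <- base::log(2) - base::log(pp$sigma) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(pp$lambda * z, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' Skew-normal cumulative distribution function
#'
#' `F(s) = Phi((s-mu)/sigma) - 2*T((s-mu)/sigma, lambda)` with `T` Owen's T
#' function.
#'
#' @inheritParams dsn
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
psn <- function(x, p = NULL, mu = 0, sigma = 1, lambda = 0) {
  pp <- norm_params(x, p, mu, sigma, lambda)
  z <- (x - pp$mu) / pp$sigma
  v <- stats::pnorm(z) - 2 * owens_t(z, pp$lambda)
  pmin(pmax(v, 0), 1)
}

#' Skew-normal survival function
#'
#' `S(s) = 1 - F(s)`, the probability that a component score exceeds `s`.
#'
#' @inheritParams dsn
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
ssn <- function(x, p = NULL, mu = 0, sigma = 1, lambda = 0) {
  pp <- norm_params(x, p, mu, sigma, lambda)
  z <- (x - pp$mu) / pp$sigma
  # 1 - F written with the upper-tail normal for accuracy in the right tail:
  # S = Phi(-z) + 2*T(z, lambda)
  v <- stats::pnorm(z, lower.tail = FALSE) + 2 * owens_t(z, pp$lambda)
  pmin(pmax(v, 0), 1)
}

#' Sample from a skew-normal distribution
#'
#' Draws through the stochastic representation
#' `S = mu + Delta*T + sqrt(Gamma)*U`, `T ~ TN+(0,1)`, `U ~ N(0,1)`.
#'
#' @param n number of draws.
#' @param p an [sn_params()] object (or supply `mu`, `sigma`, `lambda`).
#' @inheritParams dsn
#' @param seed optional integer; when given, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @export
rsn <- function(n, p = NULL, mu = 0, sigma = 1, lambda = 0, seed = NULL) {
  stopifnot(n >= 1)
  pp <- norm_params(NULL, p, mu, sigma, lambda)
  a <- to_alternate(sn_params(pp$mu, pp$sigma, pp$lambda))
  with_seed(seed, {
    t_pos <- abs(stats::rnorm(n))
    u <- stats::rnorm(n)
    a$mu + a$Delta * t_pos + sqrt(a$Gamma) * u
  })
}

#' Numeric mode of a skew-normal density
#'
#' The SN density is unimodal but its mode has no closed form. The
#' standardized mode `z*` solves the score equation
#' `z = lambda * r(lambda * z)` with `r` the inverse Mills ratio; it is
#' found by safeguarded Newton iteration (bisection fallback), with a
#' bounded golden-section maximization of the log-density on
#' `[mu - 5*sigma, mu + 5*sigma]` as a backstop.
#'
#' @param p an [sn_params()] object.
#' @param tol absolute tolerance of the maximizer, in units of `sigma`.
#' @return The mode (a score).
#' @export
sn_mode <- function(p, tol = 1e-10) {
  stopifnot(inherits(p, "sn_params"))
  if (p$lambda == 0) return(p$mu)
  al <- abs(p$lambda)
  mills <- function(x) exp(stats::dnorm(x, log = TRUE) -
                             stats::pnorm(x, log.p = TRUE))
  h <- function(z) -z + al * mills(al * z)   # d/dz log density, standardized
  lo <- 0; hi <- min(al * mills(0), 1) + 1e-3   # h(lo) > 0, h(hi) < 0
  while (h(hi) > 0) hi <- hi * 2
  z <- (lo + hi) / 2
  for (it in 1:100) {
    r <- mills(al * z)
    hz <- -z + al * r
    if (hz > 0) lo <- z else hi <- z
    dh <- -1 - al^2 * r * (al * z + r)
    z_new <- z - hz / dh
    if (!is.finite(z_new) || z_new <= lo || z_new >= hi)
      z_new <- (lo + hi) / 2
    if (abs(z_new - z) < tol) { z <- z_new; break }
    z <- z_new
  }
  if (abs(h(z)) > 1e-6) {  # backstop: direct bounded maximization
    opt <- stats::optimize(function(x) dsn(x, p, log = TRUE),
                           interval = c(p$mu - 5 * p$sigma,
                                        p$mu + 5 * p$sigma),
                           maximum = TRUE, tol = tol * p$sigma)
    return(opt$maximum)
  }
  p$mu + sign(p$lambda) * z * p$sigma
}

#' Conditional truncated-normal moments of the stochastic representation
#'
#' Given an SN score `s`, the latent `TN+(0,1)` variable of the stochastic
#' representation has conditional law `TN+(alpha, psi^2)` with
#' `alpha = (delta/sigma)*(s - mu)` and `psi^2 = 1 - delta^2`. Returns its
#' first two moments,
#' `xi1 = alpha + psi*r` and `xi2 = alpha^2 + psi^2 + alpha*psi*r`, where
#' `r = phi(alpha/psi)/Phi(alpha/psi)` is the inverse Mills ratio, computed
#' in log space so it is stable far into the left tail.
#'
#' @param s numeric vector of scores.
#' @param p an [sn_params()] object.
#' @return A list with numeric vectors `xi1` and `xi2`.
#' @export
tn_moments <- function(s, p) {
  stopifnot(inherits(p, "sn_params"))
  m <- cpp_tn_moments(s, p$mu, p$sigma, p$lambda)
  list(xi1 = m[, 1L], xi2 = m[, 2L])
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state.
#' With `seed = NULL` the expression is evaluated under the current state.
#' All seeded package functions route their randomness through this helper.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic child seed
#'
#' Maps a root seed and an index to a derived seed below `2^31`, so that
#' independent sub-experiments (restarts, bootstrap replicates, simulation
#' batches) each get a reproducible stream from one root seed.
#'
#' @param seed root integer seed.
#' @param k child index.
#' @return A numeric seed suitable for [set.seed()].
#' @export
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483587
}
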