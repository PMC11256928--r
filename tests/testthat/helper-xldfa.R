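# Shared fixtures, built in code.

# A small chain-feasible model on the default synthetic score scale.
toy_model <- function(v_phi = 0.25) default_scenario(v_phi = v_phi)

# Random SN parameters over a broad but numerically tame range.
random_sn <- function() {
  sn_params(mu = stats::runif(1, -5, 5),
            sigma = stats::runif(1, 0.3, 4),
            lambda = stats::runif(1, -6, 6))
}

# A random valid two-sample model with well separated components (used where
# only container/likelihood algebra is under test, not chain feasibility).
random_model <- function(v_phi = stats::runif(1, 0, 0.6)) {
  mus <- sort(stats::runif(5, 0, 40), decreasing = TRUE)
  theta <- stats::setNames(lapply(1:5, function(i)
    sn_params(mus[i], stats::runif(1, 1, 6), stats::runif(1, -3, 3))),
    c("C", "J1", "J2", "I1", "I2"))
  w <- stats::runif(3, 0.2, 1); w <- w / sum(w)
  v <- stats::runif(5, 0.2, 1); v <- v / sum(v)
  two_sample_model(theta, stats::setNames(w, c("C", "J1", "I1")),
                   stats::setNames(v, c("C", "J1", "J2", "I1", "I2")),
                   v_phi)
}

random_dataset <- function(n = 50, v_phi = 0.3) {
  s1 <- stats::rnorm(n, 20, 6)
  s2 <- s1 - abs(stats::rnorm(n, 2, 1))
  s2[stats::runif(n) < v_phi] <- NA
  score_dataset(s1, s2)
}

# Chain-feasible random model generator for update-step tests: common scale,
# shared negative shape below the correct component, locations separated by
# at least one scale unit.
feasible_random_model <- function(v_phi = 0) {
  repeat {
    sig <- stats::runif(1, 2, 5)
    gaps <- stats::runif(4, 1, 2) * sig
    mus <- 30 - cumsum(c(0, gaps))
    lamC <- stats::runif(1, 0.5, 2)
    lam_low <- -stats::runif(1, 0.5, 2)
    theta <- stats::setNames(
      lapply(1:5, function(i)
        sn_params(mus[i], sig, if (i == 1) lamC else lam_low)),
      c("C", "J1", "J2", "I1", "I2"))
    if (check_chain(theta)$ok) break
  }
  w <- stats::runif(3, 0.5, 1); w <- w / sum(w)
  v <- stats::runif(5, 0.5, 1); v <- v / sum(v)
  two_sample_model(theta, stats::setNames(w, c("C", "J1", "I1")),
                   stats::setNames(v, c("C", "J1", "J2", "I1", "I2")),
                   v_phi)
}

# Generic constrained-optimization oracle for the weight subproblem, via
# constrOptim on the free coordinates (wC, wJ1, vC, vJ1, vJ2, vI1).
# Returns NULL when the barrier method cannot be completed (optimum exactly
# on a boundary at the tightest stop).
kkt_oracle <- function(A, B, v_phi) {
  expand <- function(x) {
    w <- c(C = x[1], J1 = x[2], I1 = 1 - x[1] - x[2])
    v <- c(C = x[3], J1 = x[4], J2 = x[5], I1 = x[6],
           I2 = 1 - sum(x[3:6]))
    list(w = w, v = v)
  }
  slack_all <- function(x) {
    p <- expand(x)
    unname(c(xldfa:::weight_slack_B(p$w, p$v, v_phi), p$w, p$v))
  }
  x0 <- rep(0, 6)
  c0 <- slack_all(x0)
  M <- sapply(1:6, function(j) slack_all(replace(x0, j, 1)) - c0)
  obj <- function(x) {
    p <- expand(x)
    -(sum(A * log(p$w)) + sum(B * log(p$v)))
  }
  gr <- function(x) {
    p <- expand(x)
    dw <- A / p$w; dv <- B / p$v
    -c(dw[1] - dw[3], dw[2] - dw[3],
       dv[1] - dv[5], dv[2] - dv[5], dv[3] - dv[5], dv[4] - dv[5])
  }
  start <- c(1 / 3, 1 / 3, 0.2, 0.2, 0.2, 0.2)
  stopifnot(all(c0 + M %*% start > 0))
  res <- NULL
  for (eps in c(1e-12, 1e-10, 1e-8)) {
    res <- tryCatch(
      constrOptim(start, obj, gr, ui = M, ci = -c0, mu = 1e-6,
                  outer.eps = eps, outer.iterations = 200,
                  control = list(reltol = 1e-15, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(res)) break
  }
  if (is.null(res)) return(NULL)
  expand(res$par)
}

# Memoized expensive fits shared by acceptance-level tests.
.fit_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) assign(key, expr, envir = .fit_cache)
  get(key, envir = .fit_cache)
}
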