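test_that("iterated single-component updates reach the skew-normal MLE", {
  set.seed(51)
  truth <- sn_params(10, 2, 1.5)
  x <- rsn(5000, truth, seed = 99)
  # drive the closed-form updates with unit responsibilities, no constraints
  ctrl <- xldfa:::default_control()
  th <- list(C = sn_params(mean(x), sd(x), 0.5))
  modes <- c(C = sn_mode(th$C))
  for (it in 1:3000) {
    old <- th$C
    res <- xldfa:::update_one_component("C", rep(1, length(x)), x, th$C,
                                        th, modes, pairs = list(), ctrl)
    th <- res$theta; modes <- res$modes
    if (abs(th$C$mu - old$mu) < 1e-10 &&
        abs(th$C$sigma - old$sigma) < 1e-10 &&
        abs(th$C$lambda - old$lambda) < 1e-10) break
  }
  # generic numeric MLE oracle on the canonical parametrization; the SN
  # likelihood always has a stationary point at lambda = 0, so the oracle
  # is multi-started across shape values and the best optimum kept
  nll <- function(par) -sum(dsn(x, mu = par[1], sigma = exp(par[2]),
                                lambda = par[3], log = TRUE))
  opts <- lapply(c(-2, -0.5, 0.5, 2), function(l0)
    optim(c(mean(x), log(sd(x)), l0), nll, method = "BFGS",
          control = list(reltol = 1e-14, maxit = 2000)))
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  expect_equal(th$C$mu, opt$par[1], tolerance = 1e-4)
  expect_equal(th$C$sigma, exp(opt$par[2]), tolerance = 1e-4)
  expect_equal(th$C$lambda, opt$par[3], tolerance = 1e-3)
  # and the ECM fixed point is at least as likely as the oracle's optimum
  ecm_nll <- nll(c(th$C$mu, log(th$C$sigma), th$C$lambda))
  expect_lte(ecm_nll, opt$value + 1e-6 * abs(opt$value))
})

test_that("with zero current skew the location update is the
           responsibility-weighted mean", {
  set.seed(52)
  m <- feasible_random_model()
  m$theta$C <- sn_params(m$theta$C$mu, m$theta$C$sigma, 0)   # Delta_bar = 0
  ds <- strip_labels(sample_mixture_faithful(m, 400, seed = 5))
  resp <- responsibilities(m, ds)
  newC <- ecm_update_component("C", ds, resp, m)
  rw <- c(resp$omega[, "C"], resp$nu[, "C"])
  ss <- c(ds$s1, ds$s2[!is.na(ds$s2)])
  expect_equal(newC$mu, sum(rw * ss) / sum(rw), tolerance = 1e-10)
})

test_that("every single-parameter update does not decrease the Q-function", {
  set.seed(53)
  n_checked <- 0
  for (i in 1:100) {
    cur <- feasible_random_model(v_phi = runif(1, 0, 0.5))
    ds <- strip_labels(sample_mixture_faithful(cur, 80, seed = 1000 + i))
    resp <- responsibilities(cur, ds)
    model_work <- cur
    q_prev <- q_function(model_work, cur, ds)
    for (nm in c("C", "J1", "J2", "I1", "I2")) {
      tr <- ecm_update_component(nm, ds, resp, model_work, trace = TRUE)
      for (stage in tr) {
        cand <- model_work
        cand$theta <- stage
        q_now <- q_function(cand, cur, ds)
        expect_gte(q_now, q_prev - 1e-8)
        q_prev <- q_now
        n_checked <- n_checked + 1
      }
      model_work$theta <- tr[[length(tr)]]
    }
  }
  expect_gte(n_checked, 100)
})

test_that("one unconstrained iteration equals a textbook skew-normal
           mixture EM iteration", {
  set.seed(54)
  m <- feasible_random_model(v_phi = 0.3)
  ds <- strip_labels(sample_mixture_faithful(m, 500, seed = 8))
  # textbook oracle: direct Bayes responsibilities, conditional
  # truncated-normal moments and closed-form updates, no constraint
  # machinery
  s1 <- ds$s1; s2 <- ds$s2[!is.na(ds$s2)]
  comps <- c("C", "J1", "J2", "I1", "I2")
  dens1 <- sapply(c("C", "J1", "I1"), function(nm)
    m$w[[nm]] * dsn(s1, m$theta[[nm]]))
  om <- dens1 / rowSums(dens1)
  dens2 <- sapply(comps, function(nm) m$v[[nm]] * dsn(s2, m$theta[[nm]]))
  nu <- dens2 / rowSums(dens2)
  oracle_theta <- list()
  for (nm in comps) {
    p <- m$theta[[nm]]
    delta <- p$lambda / sqrt(1 + p$lambda^2)
    Delta <- p$sigma * delta; Gamma <- p$sigma^2 - Delta^2
    xi <- function(s) {
      al <- delta * (s - p$mu) / p$sigma; psi <- sqrt(1 - delta^2)
      r <- dnorm(al / psi) / pnorm(al / psi)
      list(x1 = al + psi * r, x2 = al^2 + psi^2 + al * psi * r)
    }
    if (nm %in% c("C", "J1", "I1")) {
      rw <- c(om[, nm], nu[, nm]); ss <- c(s1, s2)
    } else {
      rw <- nu[, nm]; ss <- s2
    }
    mo <- xi(ss)
    mu_n <- sum(rw * (ss - Delta * mo$x1)) / sum(rw)
    D_n <- sum(rw * mo$x1 * (ss - mu_n)) / sum(rw * mo$x2)
    G_n <- sum(rw * ((ss - mu_n)^2 - 2 * D_n * mo$x1 * (ss - mu_n) +
                       D_n^2 * mo$x2)) / sum(rw)
    oracle_theta[[nm]] <- c(mu = mu_n,
                            sigma = sqrt(G_n + D_n^2),
                            lambda = sign(D_n) * sqrt(D_n^2 / G_n))
  }
  oracle_w <- colSums(om) / length(s1)
  oracle_v <- colSums(nu) / length(s2)

  st <- ecm_step(m, ds)
  expect_equal(st$max_active, 0L)  # instance engineered to bind nothing
  for (nm in comps) {
    p <- st$model$theta[[nm]]
    expect_equal(p$mu, oracle_theta[[nm]][["mu"]], tolerance = 1e-9)
    expect_equal(p$sigma, oracle_theta[[nm]][["sigma"]], tolerance = 1e-9)
    expect_equal(p$lambda, oracle_theta[[nm]][["lambda"]], tolerance = 1e-9)
  }
  expect_equal(unname(st$model$w), unname(oracle_w), tolerance = 1e-12)
  expect_equal(unname(st$model$v), unname(oracle_v), tolerance = 1e-12)
})

test_that("unconstrained KKT solution is the responsibility averages", {
  A <- c(C = 300, J1 = 250, I1 = 450)
  B <- c(C = 20, J1 = 180, J2 = 150, I1 = 400, I2 = 250)
  sol <- solve_weights_kkt(A, B, v_phi = 0.2)
  expect_equal(sol$level, 0L)
  expect_equal(unname(sol$w), unname(A / sum(A)), tolerance = 1e-14)
  expect_equal(unname(sol$v), unname(B / sum(B)), tolerance = 1e-14)
  expect_true(all(sol$eta == 0))

  # uniform responsibilities give uniform weights
  solu <- solve_weights_kkt(
    c(C = 100, J1 = 100, I1 = 100),
    c(C = 60, J1 = 60, J2 = 60, I1 = 60, I2 = 60), v_phi = 0)
  expect_equal(unname(solu$w), rep(1 / 3, 3), tolerance = 1e-14)
  expect_equal(unname(solu$v), rep(1 / 5, 5), tolerance = 1e-14)
})

test_that("constrained KKT solutions match a generic constrained optimizer", {
  set.seed(55)
  n_binding <- 0
  for (i in 1:50) {
    # engineered so the unconstrained optimum violates b1 (wC too large)
    A <- c(C = runif(1, 0.55, 0.8), J1 = runif(1, 0.1, 0.25),
           I1 = runif(1, 0.1, 0.25)) * 1000
    B <- c(C = runif(1, 0.05, 0.2), J1 = runif(1, 0.05, 0.2),
           J2 = runif(1, 0.1, 0.3), I1 = runif(1, 0.05, 0.2),
           I2 = runif(1, 0.1, 0.3)) * 800
    v_phi <- runif(1, 0, 0.3)
    unc <- check_weights_B(A / sum(A), B / sum(B), v_phi)
    if (unc$satisfied) next
    sol <- solve_weights_kkt(A, B, v_phi)
    orc <- kkt_oracle(A, B, v_phi)
    if (!is.null(orc)) {
      n_binding <- n_binding + 1
      expect_equal(unname(sol$w), unname(orc$w), tolerance = 1e-6)
      expect_equal(unname(sol$v), unname(orc$v), tolerance = 1e-6)
    }
    # KKT conditions: stationarity residual and complementary slackness
    expect_lt(sol$residual, 1e-8)
    sl <- xldfa:::weight_slack_B(sol$w, sol$v, v_phi)
    expect_true(all(abs(sol$eta * sl) < 1e-6))
    expect_true(check_weights_B(sol$w, sol$v, v_phi, tol = 1e-8)$satisfied)
  }
  expect_gte(n_binding, 25)
})

test_that("random initialization satisfies its stated contract", {
  set.seed(56)
  m <- toy_model(v_phi = 0.2)
  ds <- strip_labels(sample_mixture_faithful(m, 500, seed = 2))
  for (l0 in c(1, 2)) {
    init <- with_seed(100 + l0, init_params(ds, lambda0 = l0, sign_J1 = -1))
    expect_true(check_chain(init$theta)$ok)
    # exact prescribed starting weights
    expect_equal(unname(init$w), rep(1 / 3, 3), tolerance = 1e-15)
    expect_equal(unname(init$v), c(0.001, rep(0.999 / 4, 4)),
                 tolerance = 1e-15)
    # locations sorted descending C >= J1 >= J2 >= I1 >= I2
    mus <- vapply(init$theta, function(p) p$mu, numeric(1))
    expect_true(all(diff(mus) <= 0))
    # prescribed skewness signs
    lam <- vapply(init$theta, function(p) p$lambda, numeric(1))
    expect_gt(lam[["C"]], 0)
    expect_lt(lam[["J1"]], 0)
    expect_true(all(lam[c("J2", "I1", "I2")] < 0))
    if (l0 == 1) expect_equal(unname(abs(lam)), rep(1, 5), tolerance = 1e-12)
    expect_equal(init$v_phi, compute_v_phi(ds))
  }
})

test_that("the restart structure yields the documented initialization count", {
  expect_identical(n_initializations(), 240L)
  expect_identical(n_initializations(rounds = 1), 6L)
})

test_that("the exhaustive KKT active-set enumeration has 256 systems", {
  expect_identical(kkt_system_count(), 256L)
})

test_that("small fits are reproducible and respect the constraints", {
  set.seed(57)
  m <- toy_model(v_phi = 0.2)
  ds <- strip_labels(sample_mixture_faithful(m, 600, seed = 3))
  f1 <- fit_xl_mixture(ds, n_restarts = 2, seed = 42, max_iter = 25,
                       tol = 1e-6)
  f2 <- fit_xl_mixture(ds, n_restarts = 2, seed = 42, max_iter = 25,
                       tol = 1e-6)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$loglik, f2$loglik)

  expect_true(check_chain(f1$model$theta)$ok)
  expect_true(check_weights_B(f1$model$w, f1$model$v,
                              f1$model$v_phi)$satisfied)
  # observed log-likelihood increases over the run
  expect_gte(f1$loglik, f1$loglik_trace[1])
  # and is non-decreasing wherever no weight constraint was active
  if (f1$max_active == 0)
    expect_true(all(diff(f1$loglik_trace) > -1e-6))
})

test_that("the one-sample fit uses unconstrained weight updates and the
           short chain", {
  set.seed(58)
  m <- toy_model(v_phi = 1)   # all second scores missing
  ds <- strip_labels(sample_mixture_faithful(m, 800, seed = 4))
  expect_equal(compute_v_phi(ds), 1)
  f <- fit_one_sample(ds, n_restarts = 2, seed = 7, max_iter = 40,
                      tol = 1e-7)
  expect_s3_class(f$model, "one_sample_model")
  expect_true(check_chain(f$model$theta,
                          pairs = list(c("C", "J1"), c("J1", "I1")))$ok)
  # weight update is exactly the E-step responsibility average
  resp <- responsibilities(f$model, ds)
  st <- ecm_step(f$model, ds)
  expect_equal(unname(st$model$w),
               unname(colSums(resp$omega) / nrow(ds)),
               tolerance = 1e-12)
})

test_that("with idle runner-up components the two-sample update reduces to
           the one-sample update on all-missing data", {
  set.seed(59)
  ds <- score_dataset(rnorm(500, 24, 6))   # every second score missing
  theta5 <- toy_model()$theta
  m2 <- two_sample_model(theta5, c(C = 1, J1 = 1, I1 = 1) / 3,
                         stats::setNames(c(0.001, rep(0.999 / 4, 4)),
                                         c("C", "J1", "J2", "I1", "I2")),
                         v_phi = 1)
  m1 <- one_sample_model(theta5[c("C", "J1", "I1")],
                         c(C = 1, J1 = 1, I1 = 1) / 3)
  s2 <- ecm_step(m2, ds)
  s1 <- ecm_step(m1, ds)
  # J2/I2 carry no evidence: frozen in place
  expect_identical(s2$model$theta$J2, theta5$J2)
  expect_identical(s2$model$theta$I2, theta5$I2)
  expect_equal(loglik(s2$model, ds), loglik(s1$model, ds), tolerance = 1e-6)
})
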