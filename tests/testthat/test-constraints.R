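test_that("weight constraint set B evaluates the stated inequalities", {
  w <- c(C = 1, J1 = 1, I1 = 1) / 3
  v <- c(C = 0.001, J1 = 0.24975, J2 = 0.24975, I1 = 0.24975, I2 = 0.24975)
  rep <- check_weights_B(w, v, v_phi = 0)
  # checked by hand: wC = 1/3 <= vJ1 + vI1 = 0.4995, the two other top
  # bounds are even looser, and each second-score weight is below its bound
  expect_true(rep$satisfied)
  expect_length(rep$violated, 0)

  w_bad <- c(C = 0.9, J1 = 0.05, I1 = 0.05)
  v_unif <- stats::setNames(rep(0.2, 5), names(v))
  rep2 <- check_weights_B(w_bad, v_unif, v_phi = 0)
  expect_false(rep2$satisfied)
  expect_true("b1" %in% rep2$violated)   # 0.9 > 0.2 + 0.2

  # with v_phi = 0 set B reduces exactly to set A
  set.seed(31)
  for (i in 1:20) {
    w_r <- stats::runif(3); w_r <- stats::setNames(w_r / sum(w_r), names(w))
    v_r <- stats::runif(5); v_r <- stats::setNames(v_r / sum(v_r), names(v))
    expect_identical(check_weights_B(w_r, v_r, 0)$violated,
                     check_weights_A(w_r, v_r)$violated)
  }

  # missingness loosens the top-score bounds: a weight vector violating
  # set A can satisfy set B at high v_phi
  expect_false(check_weights_A(w_bad, v_unif)$satisfied)
  expect_true(check_weights_B(w_bad, v_unif, v_phi = 0.9)$satisfied)
})

test_that("density dominance holds for shifted equal-shape pairs and is
           irreflexive", {
  f <- sn_params(1, 1, 0)
  g <- sn_params(0, 1, 0)
  expect_true(check_dominance(f, g))
  expect_false(check_dominance(g, f))
  expect_false(check_dominance(f, f))    # strict order: mode(f) > mode(g) fails
})

test_that("density dominance agrees with a dense-grid oracle", {
  grid_oracle <- function(f, g, n = 1e5) {
    mf <- sn_mode(f); mg <- sn_mode(g)
    if (!(mf > mg)) return(FALSE)
    sc <- max(f$sigma, g$sigma)
    xr <- seq(mf, mf + 12 * sc, length.out = n)
    xl <- seq(mg - 12 * sc, mg, length.out = n)
    all(dsn(xr, f, log = TRUE) > dsn(xr, g, log = TRUE)) &&
      all(dsn(xl, g, log = TRUE) > dsn(xl, f, log = TRUE))
  }
  # unequal scales: N(1,1) vs N(0,3) must agree with the oracle
  f <- sn_params(1, 1, 0); g <- sn_params(0, 3, 0)
  expect_identical(check_dominance(f, g), grid_oracle(f, g))
  set.seed(32)
  for (i in 1:40) {
    f <- sn_params(runif(1, 0, 3), runif(1, 0.5, 3), runif(1, -3, 3))
    g <- sn_params(runif(1, -3, 0), runif(1, 0.5, 3), runif(1, -3, 3))
    expect_identical(check_dominance(f, g), grid_oracle(f, g),
                     label = sprintf("pair %d", i))
  }
})

test_that("dominance is transitive on triples that pairwise satisfy it", {
  set.seed(33)
  found <- 0
  while (found < 10) {
    ps <- lapply(c(2, 0, -2), function(m)
      sn_params(m + runif(1, -0.5, 0.5), runif(1, 0.8, 2), runif(1, -2, 2)))
    if (check_dominance(ps[[1]], ps[[2]]) &&
        check_dominance(ps[[2]], ps[[3]])) {
      expect_true(check_dominance(ps[[1]], ps[[3]]))
      found <- found + 1
    }
  }
})

test_that("the chain check reports the first violated pair", {
  theta <- stats::setNames(lapply(c(5, 4, 3, 2, 1), function(m)
    sn_params(m, 1, 0)), c("C", "J1", "J2", "I1", "I2"))
  expect_true(check_chain(theta)$ok)

  theta_bad <- theta
  theta_bad$C <- theta$J1; theta_bad$J1 <- theta$C
  res <- check_chain(theta_bad)
  expect_false(res$ok)
  expect_equal(res$violated, c("C", "J1"))

  # the one-sample chain only involves C, J1, I1
  expect_true(check_chain(theta[c("C", "J1", "I1")],
                          pairs = list(c("C", "J1"), c("J1", "I1")))$ok)
})

test_that("binary-search repair returns feasible candidates unchanged and
           repairs infeasible ones to the boundary", {
  theta <- toy_model()$theta
  expect_true(check_chain(theta)$ok)

  # feasible candidate passes through
  out <- binary_search_repair("C", "mu", theta$C$mu, theta$C$mu + 1, theta)
  expect_equal(out, theta$C$mu + 1)

  # pushing mu_C far below J1 must break (C, J1); repaired value lies
  # strictly between and is feasible
  cand <- theta$J1$mu - 10
  out <- binary_search_repair("C", "mu", theta$C$mu, cand, theta)
  expect_gt(out, cand)
  expect_lt(out, theta$C$mu)
  theta2 <- theta
  theta2$C <- sn_params(out, theta$C$sigma, theta$C$lambda)
  expect_true(check_chain(theta2)$ok)

  # infeasible starting point violates the contract
  theta_bad <- theta
  theta_bad$C <- sn_params(theta$J1$mu - 10, theta$C$sigma, theta$C$lambda)
  expect_error(
    binary_search_repair("C", "mu", theta_bad$C$mu, theta$C$mu, theta_bad),
    "not feasible")
})

test_that("repair boundary matches a fine linear-scan oracle", {
  theta <- toy_model()$theta
  old <- theta$C$mu
  cand <- theta$J1$mu - 6
  out <- binary_search_repair("C", "mu", old, cand, theta)
  feas <- function(t) {
    th <- theta
    th$C <- sn_params(old + t * (cand - old), theta$C$sigma, theta$C$lambda)
    check_chain(th)$ok
  }
  # staged linear scan: walk a uniform grid until the first infeasible
  # point, then rescan the bracketing interval at finer resolution
  lo <- 0; hi <- 1
  for (stage in 1:3) {
    ts <- seq(lo, hi, length.out = 401)
    first_bad <- 402L
    for (j in 2:401) {
      if (!feas(ts[j])) { first_bad <- j; break }
    }
    if (first_bad > 401L) { lo <- hi; break }
    lo <- ts[first_bad - 1L]; hi <- ts[first_bad]
  }
  boundary <- old + lo * (cand - old)
  expect_lt(abs(out - boundary), 1e-8 * abs(cand - old) +
              abs(cand - old) * (1 / 400)^3)
})

test_that("repair in Delta and Gamma keeps the chain feasible", {
  theta <- toy_model()$theta
  for (param in c("Delta", "Gamma")) {
    a <- to_alternate(theta$J2)
    cand <- if (param == "Delta") a$Delta + 30 else a$Gamma * 40
    out <- binary_search_repair("J2", param, a[[param]], cand, theta)
    a2 <- a; a2[[param]] <- out
    theta2 <- theta
    theta2$J2 <- from_alternate(a2)
    expect_true(check_chain(theta2)$ok)
  }
})
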