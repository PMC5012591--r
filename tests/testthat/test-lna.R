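test_that("reaction list reproduces the deterministic derivatives", {
  p <- pathway_params()
  set.seed(4)
  for (i in 1:10) {
    st <- c(runif(1, 0, p$T_Tot), runif(1, 0, p$T_Tot),
            runif(1, 0, p$CheA_Tot), runif(1, 0, p$CheB_Tot),
            runif(1, 0, p$CheY_Tot))
    rx <- pathway_reactions(st, p)
    expect_equal(as.numeric(rx$S %*% rx$v), pathway_derivatives(st, p),
                 tolerance = 1e-12)
    expect_true(all(rx$v >= 0))
  }
  # ablated model: the three Q reactions are silent
  p0 <- pathway_params(deamidation = FALSE)
  rx0 <- pathway_reactions(c(0, 5, 0.1, 0.1, 2), p0)
  expect_equal(unname(rx0$v[c("deamidation", "Q_synthesis", "Q_dilution")]),
               c(0, 0, 0))
})

test_that("Lyapunov solver passes the birth-death Poisson oracle", {
  # production k, decay gamma: stationary variance equals the mean
  k <- 50; gam <- 0.3
  n_mean <- k / gam
  A <- matrix(-gam, 1, 1)
  B2 <- matrix(k + gam * n_mean, 1, 1)   # S diag(v) S^T at steady state
  C <- solve_lyapunov(A, B2)
  expect_equal(C[1, 1], n_mean, tolerance = 1e-12)
  # a coupled 2x2 case against a brute-force Kronecker residual
  A2 <- matrix(c(-2, 0.5, 0.3, -1), 2, 2)
  B22 <- matrix(c(4, 1, 1, 3), 2, 2)
  C2 <- solve_lyapunov(A2, B22)
  expect_equal(A2 %*% C2 + C2 %*% t(A2) + B22, matrix(0, 2, 2),
               tolerance = 1e-10)
})

test_that("pathway LNA produces a consistent stationary covariance", {
  p <- pathway_params()
  ss <- steady_state(p)
  sys <- lna_covariance(ss, p)
  expect_equal(sys$C, t(sys$C), tolerance = 1e-10)
  expect_lt(sys$residual, 1e-8)
  expect_gt(sys$var_Yp, 0)
  expect_gt(sys$tau_adapt, 0)
  expect_gte(sys$n_eff, 1L)
  # variances (diagonal) are non-negative
  expect_true(all(diag(sys$C) > -1e-8))
  # n_eff grows with the observation window
  s2 <- lna_covariance(ss, p, T_obs = 100 * sys$tau_adapt)
  expect_gt(s2$n_eff, sys$n_eff)
})

test_that("coefficient of variation falls as the system grows", {
  # system-size expansion: at fixed concentrations, CV(Y_P) ~ 1/sqrt(V)
  base <- c(CheA = 6700, CheB = 240, CheY = 8200, CheZ = 3200,
            CheR = 140, T = 15000)
  cvs <- vapply(c(1, 10, 100), function(scale) {
    # concentrations fixed: counts and volume scale together
    p <- pathway_params(counts = as.list(base * scale),
                        volume = 1.4 * scale)
    ss <- steady_state(p)
    sys <- lna_covariance(ss, p)
    sqrt(sys$var_Yp) / unname(ss$state["Y_P"])
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
  expect_equal(cvs[1] / cvs[2], sqrt(10), tolerance = 0.2)
})

test_that("short SSA run stays near the deterministic fixed point", {
  p <- pathway_params()
  ss <- steady_state(p)
  o <- ssa_pathway(ss, p, t_burnin = 20, t_sample = 80, seed = 3,
                   max_events = 1e8)
  expect_equal(o$mean[["Y_P"]] / p$omega, unname(ss$state["Y_P"]),
               tolerance = 0.05)
  # determinism under seed
  o2 <- ssa_pathway(ss, p, t_burnin = 20, t_sample = 80, seed = 3,
                    max_events = 1e8)
  expect_identical(o$var, o2$var)
})
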