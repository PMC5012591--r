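test_that("receptor activity follows the MWC logistic form", {
  p <- pathway_params()
  # bare offset when unmodified
  expect_equal(receptor_activity(0, 0, p), 1 / (1 + exp(p$eps0)))
  # one methylated site is worth two glutamines (eps2 = eps1/2)
  u <- p$T_Tot / 3
  expect_equal(receptor_activity(2 * u, 0, p),
               receptor_activity(0, 4 * u, p), tolerance = 1e-12)
  # bounded in (0, 1) and monotone with the eps1 sign
  M <- seq(0, 4 * p$T_Tot, length.out = 30)
  a <- receptor_activity(M, 0, p)
  expect_true(all(a > 0 & a < 1))
  expect_true(all(diff(a) > 0))  # eps1 < 0: methylation activates
  expect_error(receptor_activity(-1, 0, p), "non-negative")
  expect_error(receptor_activity(4 * p$T_Tot, p$T_Tot, p), "exceeds")
})

test_that("derivative terms match their printed structure", {
  p <- pathway_params()
  # fully inactive cluster: deamidation term vanishes, fixed point Q = 2T
  # (take a with M = Q = 0 small and force a = 0 via eps0 large)
  p0 <- pathway_params(eps0 = 60)
  st <- c(2 * p0$T_Tot, 0, 0, 0.1, 0)
  d <- pathway_derivatives(st, p0)
  expect_equal(d[1], 0, tolerance = 1e-12)
  st2 <- c(p0$T_Tot, 0, 0, 0.1, 0)    # below the fixed point: Q grows
  expect_gt(pathway_derivatives(st2, p0)[1], 0)
  # total CheA is conserved by construction: only A_P is a state variable,
  # and its derivative balances phosphotransfer exactly
  st3 <- c(1, 5, 0.05, 0.1, 2)
  d3 <- pathway_derivatives(st3, p)
  a <- receptor_activity(5, 1, p)
  expect_equal(d3[3] + d3[4] + d3[5],
               a * p$a_P * (p$CheA_Tot - 0.05) - p$d_B * 0.1 -
                 p$d_Z * p$CheZ * p$chez_mult * 2, tolerance = 1e-10)
})

test_that("ratio law holds in the ablated saturated regime", {
  # r = 0, Q = 0, saturated kinetics: a/(1-a) = kR R / (kB B_P) at dM = 0
  # (eps0 raised so the zero-methylation activity floor lies below the
  # ratio-determined value and the interior root exists)
  p <- pathway_params(deamidation = FALSE, r = 0, K_R = 1e-3, K_B = 1e-3,
                      eps0 = 5)
  BP <- 0.2
  ratio <- p$k_R * p$CheR / (p$k_B * BP)
  a_pred <- ratio / (1 + ratio)
  # find M where dM/dt = 0 given B_P
  f <- function(M) {
    st <- c(0, M, 0, BP, 0)
    pathway_derivatives(st, p)[2]
  }
  M0 <- stats::uniroot(f, c(1e-6, 4 * p$T_Tot * 0.999))$root
  expect_equal(receptor_activity(M0, 0, p), a_pred, tolerance = 1e-3)
  # scaling CheR and CheB_P by a common factor leaves activity unchanged
  p2 <- p; p2$CheR <- p$CheR * 3
  f2 <- function(M) pathway_derivatives(c(0, M, 0, 3 * BP, 0), p2)[2]
  M2 <- stats::uniroot(f2, c(1e-6, 4 * p$T_Tot * 0.999))$root
  expect_equal(receptor_activity(M2, 0, p2),
               receptor_activity(M0, 0, p), tolerance = 1e-3)
})

test_that("steady state satisfies tolerance, stability and the oracle", {
  p <- pathway_params()
  ss <- steady_state(p)
  expect_lt(ss$residual, 1e-10)
  expect_true(ss$stable)
  expect_true(all(ss$state >= 0))
  expect_lte(ss$state["Q"] + ss$state["M"], 4 * p$T_Tot)
  # integration oracle: long relaxation from the QEQE state lands on the
  # same fixed point
  f <- function(y) pathway_derivatives(y, p)
  y0 <- c(2 * p$T_Tot, 0, 0, 0, 0)
  yT <- ode_integrate(f, y0, c(0, 2e5), rtol = 1e-9, atol = 1e-12)[2, ]
  expect_equal(unname(ss$state), yT, tolerance = 1e-5)
})

test_that("no CheB means no deamidation: steady Q = 2 T_Tot", {
  p <- pathway_params()
  p$CheB_Tot <- 0
  ss <- steady_state(p)
  expect_equal(unname(ss$state["Q"]), 2 * p$T_Tot, tolerance = 1e-9)
})

test_that("tumble bias readouts are monotone in CheY-P", {
  mp <- motor_params()
  yp <- seq(0, 15, 0.5)
  for (m in c("adaptive", "direct")) {
    tb <- tumble_bias_from_Yp(yp, mp, motor = m)
    expect_true(all(diff(tb) >= 0))
    expect_true(all(tb >= 0 & tb <= 1))
  }
  expect_equal(tumble_bias_from_Yp(mp$K_D, mp, motor = "direct"), 0.5)
})

test_that("steady TB rises with CheR and falls with CheB", {
  p <- pathway_params()
  tb_of <- function(nr, nb) {
    pi <- p
    pi$CheR <- nr / p$omega
    pi$CheB_Tot <- nb / p$omega
    ss <- steady_state(pi)
    tumble_bias_from_Yp(unname(ss$state["Y_P"]))
  }
  tb_r <- vapply(c(30, 100, 300, 1000), tb_of, numeric(1), nb = 240)
  expect_true(all(diff(tb_r) > 0))
  tb_b <- vapply(c(60, 240, 1000, 4000), function(nb) tb_of(140, nb),
                 numeric(1))
  expect_true(all(diff(tb_b) < 0))
})

test_that("adaptation transient: no CheB leaves the glutamine load frozen", {
  p <- pathway_params(counts = list(CheB = 0))
  p$CheB_Tot <- 0
  tr <- adaptation_transient(p, duration = 1800, n_out = 7)
  # nothing deamidates: Q stays exactly at the synthesis level; only a
  # small residual methylation drift remains after growth arrest
  expect_lt(diff(range(tr$Q)), 1e-6)
  expect_lt(diff(range(tr$tumble_bias)), 0.02)
})
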