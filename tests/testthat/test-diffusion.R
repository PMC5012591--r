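test_that("correlation curves reproduce analytic cases", {
  # ballistic: Cv flat at s^2, MSD quadratic
  tr <- trajectory(seq(0, 50, 0.1), 20 * seq(0, 50, 0.1), rep(0, 501))
  cc <- correlation_curves(tr, max_lag = 5)
  expect_equal(cc$Cv, rep(400, length(cc$Cv)), tolerance = 1e-9)
  expect_equal(cc$MSD, (20 * cc$lags)^2, tolerance = 1e-9)
  expect_equal(cc$MSD[1], 0)
  expect_true(all(diff(cc$counts[-1]) <= 0))

  # circle of radius R at angular rate w0: Cv(dt) ~ (w0 R)^2 cos(w0 dt)
  R <- 5; w0 <- 0.8
  t <- seq(0, 200, 0.1)
  tr2 <- trajectory(t, R * cos(w0 * t), R * sin(w0 * t))
  cc2 <- correlation_curves(tr2, max_lag = 6)
  # discrete chord speed: 2R sin(w0 dt/2)/dt
  veff <- 2 * R * sin(w0 * 0.05) / 0.1
  expect_equal(cc2$Cv, veff^2 * cos(w0 * cc2$lags), tolerance = 1e-6)

  # stationary cell: both curves vanish
  tr3 <- trajectory(seq(0, 30, 0.1), rep(1, 301), rep(2, 301))
  cc3 <- correlation_curves(tr3, max_lag = 3)
  expect_true(all(cc3$Cv == 0) && all(cc3$MSD == 0))

  expect_error(correlation_curves(tr3, max_lag = 50), "duration")
})

test_that("closed-form MSD equals the Green-Kubo double integral", {
  for (v0 in c(10, 25)) for (tau in c(0.5, 2)) for (om in c(0, 1.5)) {
    t <- c(0.3, 1, 4)
    quad <- vapply(t, function(tt)
      2 * stats::integrate(function(u) (tt - u) * vacf_model(u, v0, tau, om),
                           0, tt, rel.tol = 1e-12)$value, numeric(1))
    expect_equal(msd_model(t, v0, tau, om), quad, tolerance = 1e-9)
  }
  # omega = 0 reduces to the classic persistent-walker form
  t <- seq(0.1, 5, 0.7)
  expect_equal(msd_model(t, 20, 1, 0),
               2 * 400 * 1 * (t - 1 + exp(-t)), tolerance = 1e-12)
})

test_that("joint fit recovers exact generator parameters", {
  curves <- make_curves(seq(0, 8, 0.1), 20, 1, 0)
  fit <- fit_motility_model(curves)
  expect_equal(fit$v0, 20, tolerance = 1e-6)
  expect_equal(fit$tau_persist, 1, tolerance = 1e-5)
  expect_equal(fit$omega, 0)
  expect_equal(fit$D_eff, 200, tolerance = 1e-4)
  # oscillating case: omega detected from the sign change
  curves2 <- make_curves(seq(0, 8, 0.1), 15, 2, 1.2)
  fit2 <- fit_motility_model(curves2)
  expect_equal(fit2$v0, 15, tolerance = 1e-4)
  expect_equal(fit2$omega, 1.2, tolerance = 1e-3)
  # deterministic
  expect_identical(fit_motility_model(curves2)$v0, fit2$v0)
})

test_that("D_eff is invariant under rigid rotation of the trajectory", {
  tr <- simulate_trajectory(2.8, sp = clean_swim(), duration = 120, seed = 31)
  th <- 0.7
  tr2 <- tr
  tr2$x <- cos(th) * tr$x - sin(th) * tr$y
  tr2$y <- sin(th) * tr$x + cos(th) * tr$y
  f1 <- fit_motility_model(correlation_curves(tr, max_lag = 8))
  f2 <- fit_motility_model(correlation_curves(tr2, max_lag = 8))
  expect_equal(f1$D_eff, f2$D_eff, tolerance = 1e-6)
})

test_that("fitted v0 and tau match a planar tumble-free swimmer", {
  # 2D persistent random walk: heading diffuses with D_phi, so
  # Cv(t) = v^2 exp(-D_phi t) and tau = 1/D_phi
  set.seed(99)
  dt <- 0.01; v <- 20; Dphi <- 0.5
  n <- 200000
  phi <- cumsum(c(stats::runif(1, 0, 2 * pi),
                  stats::rnorm(n - 1, 0, sqrt(2 * Dphi * dt))))
  x <- cumsum(c(0, v * cos(phi[-n]) * dt))
  y <- cumsum(c(0, v * sin(phi[-n]) * dt))
  keep <- seq(1, n, 10)  # 10 Hz sampling
  tr <- trajectory((keep - 1) * dt, x[keep], y[keep])
  fit <- fit_motility_model(correlation_curves(tr, max_lag = 8))
  expect_lt(abs(fit$v0 - v) / v, 0.05)
  expect_lt(abs(fit$tau_persist - 1 / Dphi) / (1 / Dphi), 0.25)
})

test_that("run-time approximation evaluates the printed formula", {
  expect_equal(approx_diffusion(20, 1, 0, 2), 200)
  expect_equal(approx_diffusion(20, 1, 0.18, 2), 400 / (2 * 0.82))
  expect_error(approx_diffusion(20, 1, 1, 2), "singular")
  # divergence approaching the singular limit
  expect_gt(approx_diffusion(20, 1, 0.999, 2), 1e5)
})

test_that("D_apx tracks D_eff across a simulated phenotype panel", {
  trajs <- simulate_panel(c(0.1, 0.25, 0.45), n_per_level = 6,
                          duration = 150, seed = 50)
  model <- shared_model()
  summ <- summarize_cells(trajs, model)
  fits <- fit_cells_diffusion(trajs)
  merged <- merge(summ, fits, by = "cell_id")
  merged <- merged[is.finite(merged$mean_cos_turn) &
                     merged$mean_cos_turn < 1 & merged$mean_run_time > 0, ]
  dapx <- approx_diffusion(merged$mean_speed, merged$mean_run_time,
                           merged$mean_cos_turn, d = 2)
  expect_gt(stats::cor(dapx, merged$D_eff, method = "spearman"), 0.7)
})
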