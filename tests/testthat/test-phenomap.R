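make_points <- function(n = 400, seed = 1, f = function(lr, lb) 0.3) {
  set.seed(seed)
  lr <- runif(n, 1, 3.5)
  lb <- runif(n, 1, 3.5)
  data.frame(N_R = 10^lr, N_B = 10^lb, tumble_bias = f(lr, lb))
}

test_that("local linear mean reproduces constants and planes exactly", {
  pts <- make_points()
  m <- local_linear_mean(pts)
  expect_equal(range(m$value), c(0.3, 0.3), tolerance = 1e-12)
  # degree-1 exactness on an affine surface
  pts2 <- make_points(f = function(lr, lb) 0.1 + 0.07 * lr - 0.12 * lb)
  m2 <- local_linear_mean(pts2)
  truth <- outer(0.1 + 0.07 * m2$grid_R, 0.12 * m2$grid_B, `-`)
  expect_equal(m2$value, truth, tolerance = 1e-9)
})

test_that("grid fits agree with a brute-force weighted solve", {
  pts <- make_points(f = function(lr, lb) 0.2 + 0.05 * sin(lr) * lb)
  m <- local_linear_mean(pts, bandwidth = 0.3)
  # re-solve one grid point independently
  i <- 25; j <- 30
  lr <- log10(pts$N_R); lb <- log10(pts$N_B)
  sx <- sd(lr); sy <- sd(lb)
  qx <- (lr - mean(lr)) / sx - (m$grid_R[i] - mean(lr)) / sx
  qy <- (lb - mean(lb)) / sy - (m$grid_B[j] - mean(lb)) / sy
  d <- sqrt(qx^2 + qy^2)
  k <- ceiling(0.3 * nrow(pts))
  nn <- order(d)[1:k]
  w <- (1 - pmin(d[nn] / d[nn[k]], 1)^3)^3
  X <- cbind(1, qx[nn], qy[nn])
  beta <- solve(t(X * w) %*% X, t(X * w) %*% pts$tumble_bias[nn])
  expect_equal(m$value[i, j], beta[1], tolerance = 1e-9)
})

test_that("maps are linear-operator smooths and permutation invariant", {
  pts <- make_points(f = function(lr, lb) 0.2 + 0.03 * lr * lb)
  m <- local_linear_mean(pts)
  pts2 <- pts
  pts2$tumble_bias <- 2 * pts$tumble_bias + 0.5
  m2 <- local_linear_mean(pts2)
  expect_equal(m2$value, 2 * m$value + 0.5, tolerance = 1e-9)
  m3 <- local_linear_mean(pts[sample(nrow(pts)), ])
  expect_equal(m3$value, m$value, tolerance = 1e-9)
})

test_that("residual SD surface recovers planted structure", {
  set.seed(11)
  n <- 4000
  lr <- runif(n, 1, 3); lb <- runif(n, 1, 3)
  # homoscedastic case
  pts <- data.frame(N_R = 10^lr, N_B = 10^lb,
                    tumble_bias = 0.3 + rnorm(n, 0, 0.05))
  mm <- local_linear_mean(pts)
  rs <- local_residual_sd(pts, mm)
  expect_lt(abs(mean(rs$value[rs$support_mask]) - 0.05), 0.005)
  # zero residuals give a zero map
  pts0 <- data.frame(N_R = 10^lr, N_B = 10^lb, tumble_bias = 0.25)
  rs0 <- local_residual_sd(pts0, local_linear_mean(pts0))
  expect_lt(max(rs0$value, na.rm = TRUE), 1e-6)
  # SD varying only along CheB: contours align with the CheB axis
  ptsB <- data.frame(N_R = 10^lr, N_B = 10^lb,
                     tumble_bias = 0.3 + rnorm(n, 0, 0.02 + 0.04 * (lb - 1)))
  rsB <- local_residual_sd(ptsB, local_linear_mean(ptsB))
  oB <- contour_orientation(rsB)
  expect_gt(abs(oB$mean_angle_deg), 75)   # gradient along the N_B axis
})

test_that("global log-linear fit recovers generator parameters", {
  set.seed(21)
  n <- 5000
  lr <- runif(n, 1, 4); lb <- runif(n, 1, 3.5)
  tb <- 0.274 + 0.0627 * (lr - 1.60 * lb)
  pts_clean <- data.frame(N_R = 10^lr, N_B = 10^lb, tumble_bias = tb)
  f0 <- fit_loglinear(pts_clean, n_boot = 0)
  expect_equal(c(f0$a, f0$b, f0$c), c(0.274, 0.0627, 1.60),
               tolerance = 1e-6)
  # noisy recovery within bootstrap CIs
  pts <- pts_clean
  pts$tumble_bias <- tb + rnorm(n, 0, 0.05)
  f <- fit_loglinear(pts, n_boot = 300, seed = 2)
  expect_gt(0.274, f$ci["a", 1]); expect_lt(0.274, f$ci["a", 2])
  expect_gt(0.0627, f$ci["b", 1]); expect_lt(0.0627, f$ci["b", 2])
  expect_gt(1.60, f$ci["c", 1]); expect_lt(1.60, f$ci["c", 2])
  # bootstrap is seed-deterministic
  f2 <- fit_loglinear(pts, n_boot = 300, seed = 2)
  expect_identical(f$ci, f2$ci)
  # c = 1 special case matches a closed-form OLS oracle
  tb1 <- 0.2 + 0.08 * (lr - lb) + rnorm(n, 0, 0.02)
  pts1 <- data.frame(N_R = 10^lr, N_B = 10^lb, tumble_bias = tb1)
  ols <- lm(tb1 ~ I(lr - lb))
  f1 <- fit_loglinear(pts1, n_boot = 0)
  expect_equal(f1$c, 1, tolerance = 0.05)
  expect_equal(f1$b, unname(coef(ols)[2]), tolerance = 0.01)
  # unidentifiable c without CheB spread
  ptsx <- data.frame(N_R = 10^lr, N_B = 100, tumble_bias = tb1)
  expect_error(fit_loglinear(ptsx, n_boot = 0), "identifiable")
})

test_that("contour orientation matches analytic gradients", {
  set.seed(31)
  pts <- make_points(n = 800, f = function(lr, lb) lr - lb)
  m <- local_linear_mean(pts)
  o <- contour_orientation(m)
  expect_equal(o$mean_angle_deg, -45, tolerance = 1)
  expect_gt(o$dispersion, 0.99)
  # surface depending only on N_B: gradient parallel to the N_B axis
  ptsB <- make_points(n = 800, f = function(lr, lb) 0.1 * lb^2)
  oB <- contour_orientation(local_linear_mean(ptsB))
  expect_gt(abs(oB$mean_angle_deg), 85)
  # separation operator
  expect_equal(orientation_separation(o, o), 0, tolerance = 1e-9)
  expect_equal(orientation_separation(o, oB), 45, tolerance = 2)
})

test_that("map interpolation flags points outside the support", {
  pts <- make_points()
  m <- local_linear_mean(pts)
  expect_true(is.na(predict(m, 1e6, 100)))
  inside <- predict(m, 100, 100)
  expect_equal(inside, 0.3, tolerance = 1e-9)
})
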