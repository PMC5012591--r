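# shared helpers: all fixtures are generated in code

# CheY-P level that gives a target single-motor CW bias
yp_for_bias <- function(b, mp = motor_params()) {
  stats::uniroot(function(y) single_motor_cw_bias(y, mp) - b,
                 c(1e-4, 1e3))$root
}

# simulated multi-level panel: n cells per level at the given biases
simulate_panel <- function(biases, n_per_level, duration, seed,
                           sp = swim_params()) {
  mp <- motor_params()
  do.call(rbind, lapply(seq_along(biases), function(i)
    simulate_cells(rep(yp_for_bias(biases[i], mp), n_per_level), mp, sp,
                   duration = duration, seed = seed + i,
                   cell_id = sprintf("lvl%d_%04d", i, seq_len(n_per_level)))))
}

# noise-free planar parameters for clean-kinematics checks
clean_swim <- function(...) swim_params(loc_noise = 0, ...)

# shared fixtures, built once per test session (deterministic seeds)
.shared <- new.env()

shared_training_panel <- function() {
  if (is.null(.shared$panel))
    .shared$panel <- simulate_panel(c(0.15, 0.3), n_per_level = 15,
                                    duration = 60, seed = 400)
  .shared$panel
}

shared_model <- function() {
  if (is.null(.shared$model))
    .shared$model <- fit_behavior_model(shared_training_panel(), seed = 5)
  .shared$model
}

# analytic correlation curves container
make_curves <- function(lags, v0, tau, omega, dt = lags[2] - lags[1]) {
  structure(list(lags = lags, Cv = vacf_model(lags, v0, tau, omega),
                 MSD = msd_model(lags, v0, tau, omega),
                 counts = rep(1000L, length(lags)), dt = dt),
            class = "correlation_curves")
}
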