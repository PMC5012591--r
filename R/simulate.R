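#' Swimming and sampling parameters for the trajectory simulator
#'
#' Defaults reproduce the tracking experiment the simulator emulates:
#' constant run speed 20 um/s, rotational diffusion 0.062 rad^2/s, a
#' pseudo-2D chamber with reflecting boundaries 10 um apart in z, and 10 Hz
#' sampling of the 2D projection.
#'
#' @param speed Run speed (um/s).
#' @param D_rot Rotational diffusion coefficient of the heading (rad^2/s).
#' @param depth Chamber extent in z (um), reflecting boundaries.
#' @param dt_sample Output sampling interval (s).
#' @param dt_internal Integration step for heading updates (s); coerced to an
#'   exact divisor of `dt_sample`.
#' @param n_flagella Number of independent flagellar motors.
#' @param loc_noise Localization noise SD added to each sampled x and y
#'   position (um). The default 0.2 um emulates centroid detection accuracy
#'   (about a third of a camera pixel at 10x); set to 0 for noise-free
#'   kinematics.
#' @return An object of class `swim_params`.
#' @export
swim_params <- function(speed = 20, D_rot = 0.062, depth = 10,
                        dt_sample = 0.1, dt_internal = 0.01,
                        n_flagella = 1L, loc_noise = 0.2) {
  stopifnot(speed >= 0, D_rot >= 0, depth > 0,
            dt_sample > 0, dt_internal > 0, dt_internal <= dt_sample,
            n_flagella >= 1, loc_noise >= 0)
  dt_internal <- dt_sample / max(1L, round(dt_sample / dt_internal))
  structure(list(speed = speed, D_rot = D_rot, depth = depth,
                 dt_sample = dt_sample, dt_internal = dt_internal,
                 n_flagella = as.integer(n_flagella), loc_noise = loc_noise),
            class = "swim_params")
}

#' @export
print.swim_params <- function(x, ...) {
  cat(sprintf(paste0("<swim_params> speed = %g um/s, D_rot = %g rad^2/s, ",
                     "depth = %g um, dt = %g s (internal %g s), %d motor(s)\n"),
              x$speed, x$D_rot, x$depth, x$dt_sample, x$dt_internal,
              x$n_flagella))
  invisible(x)
}

#' Construct a trajectory object
#'
#' A trajectory is a data.frame with columns `cell_id`, `t` (s), `x`, `y`
#' (um) and optionally `truth_state` ("run"/"tumble" or NA when unknown).
#'
#' @param t Sample times (s), strictly increasing.
#' @param x,y Planar positions (um).
#' @param truth_state Optional per-sample state labels.
#' @param cell_id Identifier.
#' @return A `trajectory` data.frame.
#' @export
trajectory <- function(t, x, y, truth_state = NULL, cell_id = "cell_1") {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n,
            all(is.finite(t)), all(is.finite(x)), all(is.finite(y)))
  if (n > 1 && any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (is.null(truth_state)) truth_state <- rep(NA_character_, n)
  stopifnot(length(truth_state) == n)
  structure(data.frame(cell_id = rep(cell_id, n), t = t, x = x, y = y,
                       truth_state = truth_state,
                       stringsAsFactors = FALSE),
            class = c("trajectory", "data.frame"))
}

# deterministic per-cell RNG substream seed derived from (root seed, cell id)
cell_seed <- function(seed, cell_index) {
  as.integer((as.double(seed) * 48271 + as.double(cell_index) * 9973) %%
               2147483629)
}

#' Simulate one run-and-tumble trajectory
#'
#' Integrates 3D swimming under the two-state motor switching model at the
#' given CheY-P level and returns the sampled 2D projection with ground-truth
#' state labels. Identical `seed` and inputs give bit-identical output.
#'
#' @param Yp CheY-P concentration (uM).
#' @param mp [motor_params()].
#' @param sp [swim_params()].
#' @param duration Trajectory length (s).
#' @param seed Integer seed for this trajectory.
#' @param cell_id Identifier stored in the output.
#' @return A [trajectory()] with `truth_state` filled in.
#' @export
simulate_trajectory <- function(Yp, mp = motor_params(), sp = swim_params(),
                                duration = 100, seed = 1L,
                                cell_id = "cell_1") {
  stopifnot(duration > 0)
  k <- motor_switch_rates(Yp, mp)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- simulate_trajectory_cpp(k$k_to_CW, k$k_to_CCW, sp$n_flagella,
                                 sp$speed, sp$D_rot, sp$depth,
                                 sp$dt_sample, sp$dt_internal, duration)
  x <- out$x; y <- out$y
  if (sp$loc_noise > 0) {  # same seeded stream, after the C++ draws
    x <- x + stats::rnorm(length(x), 0, sp$loc_noise)
    y <- y + stats::rnorm(length(y), 0, sp$loc_noise)
  }
  tr <- trajectory(out$t, x, y,
                   truth_state = ifelse(out$tumble == 1L, "tumble", "run"),
                   cell_id = cell_id)
  # tumble occupancy of the interval starting at each sample (last is NA);
  # mean(occupancy) is the exact time-fraction ground truth
  tr$occupancy <- out$occupancy
  tr
}

#' Simulate a panel of cells
#'
#' One trajectory per entry of `Yp`; per-cell RNG substreams are derived
#' deterministically from the root seed so the panel is reproducible and
#' individual cells can be regenerated in isolation.
#'
#' @param Yp Vector of CheY-P concentrations (uM), one per cell.
#' @inheritParams simulate_trajectory
#' @return A single `trajectory` data.frame with all cells stacked
#'   (column `cell_id` distinguishes them).
#' @export
simulate_cells <- function(Yp, mp = motor_params(), sp = swim_params(),
                           duration = 100, seed = 1L,
                           cell_id = sprintf("cell_%04d", seq_along(Yp))) {
  stopifnot(length(cell_id) == length(Yp))
  out <- vector("list", length(Yp))
  for (i in seq_along(Yp)) {
    out[[i]] <- simulate_trajectory(Yp[i], mp, sp, duration,
                                    seed = cell_seed(seed, i),
                                    cell_id = cell_id[i])
  }
  res <- do.call(rbind, out)
  class(res) <- c("trajectory", "data.frame")
  res
}

#' Empirical CW fraction of a single motor (stochastic check)
#'
#' Long exact simulation of the two-state switch; converges to
#' [single_motor_cw_bias()].
#'
#' @inheritParams simulate_trajectory
#' @param t_total Simulated time (s).
#' @return Fraction of time spent CW.
#' @export
motor_cw_fraction <- function(Yp, mp = motor_params(), t_total = 1e4,
                              seed = 1L) {
  k <- motor_switch_rates(Yp, mp)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  motor_cw_fraction_cpp(k$k_to_CW, k$k_to_CCW, t_total)
}
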