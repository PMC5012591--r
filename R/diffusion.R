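# Effective diffusion estimation from the velocity autocorrelation (VACF)
# and the mean-square displacement (MSD), fitted jointly to the closed forms
#   Cv(t)  = v0^2 exp(-t/tau) cos(omega t)
#   MSD(t) = 2 * Int_0^t (t-u) Cv(u) du        (Green-Kubo, 2D)
# where omega captures circular swimming near the glass surface. The
# effective diffusion coefficient is D_eff = v0^2 tau / d with d = 2.

#' Time-averaged velocity autocorrelation and MSD of a trajectory
#'
#' @param traj A single-cell, uniformly sampled [trajectory()].
#' @param max_lag Largest lag (s); must be smaller than the track duration.
#' @return A list of class `correlation_curves`: `lags` (s), `Cv`
#'   (um^2/s^2), `MSD` (um^2), `counts` (averaging counts per lag), `dt`.
#'   `Cv[1]` (zero lag) is the mean squared instantaneous speed and
#'   `MSD[1] = 0`.
#' @export
correlation_curves <- function(traj, max_lag = NULL) {
  n <- nrow(traj)
  stopifnot(n >= 3)
  dts <- diff(traj$t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt)) stop("non-uniform sampling")
  duration <- traj$t[n] - traj$t[1]
  if (is.null(max_lag)) max_lag <- min(10, duration / 4)
  if (max_lag >= duration) stop("max_lag must be below the track duration")
  K <- floor(max_lag / dt + 1e-9)
  vx <- diff(traj$x) / dt
  vy <- diff(traj$y) / dt
  nv <- length(vx)
  Cv <- numeric(K + 1); MSD <- numeric(K + 1); counts <- integer(K + 1)
  Cv[1] <- mean(vx^2 + vy^2)
  counts[1] <- nv
  for (k in seq_len(K)) {
    i <- seq_len(nv - k)
    Cv[k + 1] <- mean(vx[i] * vx[i + k] + vy[i] * vy[i + k])
    j <- seq_len(n - k)
    MSD[k + 1] <- mean((traj$x[j + k] - traj$x[j])^2 +
                         (traj$y[j + k] - traj$y[j])^2)
    counts[k + 1] <- nv - k
  }
  structure(list(lags = (0:K) * dt, Cv = Cv, MSD = MSD, counts = counts,
                 dt = dt), class = "correlation_curves")
}

#' Closed-form VACF and MSD of the persistent circling swimmer
#'
#' `vacf_model` evaluates `v0^2 exp(-t/tau) cos(omega t)`; `msd_model`
#' evaluates its exact double time integral in two dimensions,
#' `2 Int_0^t (t-u) Cv(u) du`, computed with complex exponentials
#' (`s = -1/tau + i omega`):
#' \deqn{MSD(t) = 2 v_0^2\, \mathrm{Re}[\, -t/s + (e^{st}-1)/s^2 \,].}
#' For `omega = 0` this reduces to the classic persistent random walk form
#' `2 v0^2 tau^2 (t/tau - 1 + exp(-t/tau))`.
#'
#' @param t Times (s).
#' @param v0 Speed scale (um/s).
#' @param tau Persistence time (s).
#' @param omega Circling angular frequency (rad/s).
#' @return Numeric vector.
#' @export
vacf_model <- function(t, v0, tau, omega = 0) {
  v0^2 * exp(-t / tau) * cos(omega * t)
}

#' @rdname vacf_model
#' @export
msd_model <- function(t, v0, tau, omega = 0) {
  s <- complex(real = -1 / tau, imaginary = omega)
  2 * v0^2 * Re(-t / s + (exp(s * t) - 1) / s^2)
}

#' Jointly fit the motility model to VACF and MSD curves
#'
#' Minimizes the sum of squared residuals of both curves, each normalized by
#' its own scale (`Cv(0)` and `MSD(max_lag)`) so neither dominates. Starting
#' values: `v0 = sqrt(Cv(0))`, `tau` from the first lag where the VACF drops
#' below `Cv(0)/e`, `omega` from the first zero crossing (0 if none). When
#' the VACF shows no sign change, `omega` is pinned to 0 and only
#' `(v0, tau)` are fitted. The fit is deterministic given the curves.
#'
#' @param curves A [correlation_curves()] object.
#' @return A one-row data.frame of class `motility_fit`: `v0`, `tau_persist`,
#'   `omega`, `D_eff = v0^2 tau / 2`, `fit_quality` (residual norm),
#'   `converged`.
#' @export
fit_motility_model <- function(curves) {
  lags <- curves$lags
  Cv <- curves$Cv
  MSD <- curves$MSD
  cv0 <- Cv[1]
  msd_scale <- max(MSD[length(MSD)], .Machine$double.eps)
  if (!is.finite(cv0) || cv0 <= 0) stop("degenerate curves: Cv(0) <= 0")
  v0_start <- sqrt(cv0)
  below <- which(Cv < cv0 / exp(1))
  tau_start <- if (length(below)) max(lags[below[1]], curves$dt) else
    max(lags[length(lags)] / 2, curves$dt)
  zc <- which(Cv < 0)
  omega_start <- if (length(zc)) pi / (2 * max(lags[zc[1]], curves$dt)) else 0
  fit_omega <- length(zc) > 0
  obj <- function(par) {
    v0 <- exp(par[1]); tau <- exp(par[2])
    om <- if (fit_omega) par[3] else 0
    r1 <- (vacf_model(lags, v0, tau, om) - Cv) / cv0
    r2 <- (msd_model(lags, v0, tau, om) - MSD) / msd_scale
    sum(r1^2) + sum(r2^2)
  }
  p0 <- c(log(v0_start), log(tau_start))
  if (fit_omega) p0 <- c(p0, omega_start)
  lower <- c(-Inf, -Inf, if (fit_omega) 0)
  upper <- c(Inf, Inf, if (fit_omega) pi / curves$dt * 0.999)
  opt <- stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = 1000, factr = 10,
                                     pgtol = 1e-12))
  # derivative-free polish: numerical gradients limit L-BFGS-B precision
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-15))
  if (opt2$value <= opt$value) opt[c("par", "value")] <-
    opt2[c("par", "value")]
  v0 <- exp(opt$par[1]); tau <- exp(opt$par[2])
  omega <- if (fit_omega) abs(opt$par[3]) else 0
  structure(data.frame(v0 = v0, tau_persist = tau, omega = omega,
                       D_eff = v0^2 * tau / 2,
                       fit_quality = sqrt(opt$value),
                       converged = opt$convergence == 0),
            class = c("motility_fit", "data.frame"))
}

#' Run-time approximation of the diffusion coefficient
#'
#' \deqn{D_{apx} = v^2 T / (d (1 - \theta))}
#' with `v` the mean speed, `T` the mean run time between tumbles, `theta`
#' the mean cosine of the tumble angles and `d` the dimensionality.
#'
#' @param mean_speed Mean speed (um/s).
#' @param mean_run_time Mean run time (s).
#' @param mean_cos_turn Mean cosine of tumble angles; must be < 1.
#' @param d Dimensionality (default 2).
#' @return Diffusion coefficient (um^2/s).
#' @export
approx_diffusion <- function(mean_speed, mean_run_time, mean_cos_turn = 0,
                             d = 2) {
  if (any(mean_cos_turn >= 1)) stop("mean_cos_turn must be < 1 (singular)")
  mean_speed^2 * mean_run_time / (d * (1 - mean_cos_turn))
}

#' Per-cell diffusion fits for a batch of trajectories
#'
#' @param trajs Stacked trajectory table.
#' @param max_lag Largest lag (s); default `min(10, duration/4)` per cell.
#' @return A data.frame with one row per cell: the [fit_motility_model()]
#'   columns.
#' @export
fit_cells_diffusion <- function(trajs, max_lag = NULL) {
  ids <- unique(trajs$cell_id)
  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    tr <- trajs[trajs$cell_id == ids[j], , drop = FALSE]
    fit <- fit_motility_model(correlation_curves(tr, max_lag))
    fit$cell_id <- ids[j]
    out[[j]] <- fit[, c("cell_id", setdiff(names(fit), "cell_id"))]
  }
  do.call(rbind, out)
}
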