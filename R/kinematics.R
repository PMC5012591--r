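#' Per-frame kinematic features of a trajectory
#'
#' Computes instantaneous speed, acceleration, turn angle and angular
#' acceleration from a uniformly sampled 2D track:
#' \deqn{v_i = |r_{i+1}-r_i|/\Delta t,\quad a_i = (v_{i+1}-v_i)/\Delta t,}
#' \deqn{\alpha_i = ((\theta_{i+1}-\theta_i)-(\theta_i-\theta_{i-1}))/\Delta t^2,}
#' where \eqn{\theta_i} is the signed angle between consecutive velocity
#' vectors, wrapped to (-pi, pi].
#'
#' Index alignment: for n samples, `v[i]` spans samples i..i+1 and is defined
#' for i = 1..n-1; `a[i]` and `theta[i]` for i = 1..n-2; `alpha[i]` for
#' i = 2..n-3. Undefined entries are NA.
#'
#' @param traj A single-cell [trajectory()] with at least 4 samples.
#' @param dt_tol Relative tolerance on time-grid uniformity.
#' @return A data.frame of class `kinematics` with n-1 rows and columns
#'   `frame`, `v`, `a`, `theta`, `alpha`.
#' @export
compute_kinematics <- function(traj, dt_tol = 1e-6) {
  stopifnot(is.data.frame(traj), all(c("t", "x", "y") %in% names(traj)))
  if (length(unique(traj$cell_id)) > 1)
    stop("compute_kinematics expects a single cell")
  n <- nrow(traj)
  if (n < 4) stop("need at least 4 samples")
  dts <- diff(traj$t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > dt_tol * dt))
    stop("non-uniform time grid beyond tolerance")
  dx <- diff(traj$x); dy <- diff(traj$y)
  v <- sqrt(dx^2 + dy^2) / dt                     # i = 1..n-1
  a <- c(diff(v) / dt, NA_real_)                  # a[i], i = 1..n-2
  # signed turn angle between velocity vectors i and i+1
  cross <- dx[-(n - 1)] * dy[-1] - dy[-(n - 1)] * dx[-1]
  dot <- dx[-(n - 1)] * dx[-1] + dy[-(n - 1)] * dy[-1]
  theta <- c(atan2(cross, dot), NA_real_)         # theta[i], i = 1..n-2
  alpha <- rep(NA_real_, n - 1)
  if (n >= 5) {
    i <- 2:(n - 3)
    alpha[i] <- ((theta[i + 1] - theta[i]) - (theta[i] - theta[i - 1])) / dt^2
  }
  structure(data.frame(frame = seq_len(n - 1), v = v, a = a,
                       theta = theta, alpha = alpha),
            class = c("kinematics", "data.frame"))
}

# Feature table (v, a, alpha) for interior frames of every cell in a stacked
# trajectory table; used by the behavioral classifier.
kinematic_features <- function(trajs) {
  ids <- unique(trajs$cell_id)
  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    tr <- trajs[trajs$cell_id == ids[j], , drop = FALSE]
    kin <- compute_kinematics(tr)
    keep <- stats::complete.cases(kin[, c("v", "a", "alpha")])
    if (!any(keep)) next
    out[[j]] <- data.frame(cell_id = ids[j], frame = kin$frame[keep],
                           n_samples = nrow(tr),
                           v = kin$v[keep], a = kin$a[keep],
                           alpha = kin$alpha[keep],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
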