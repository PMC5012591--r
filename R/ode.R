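# Minimal stiff integrator: adaptive semi-implicit (backward Euler) steps
# with Richardson extrapolation (one full step vs two half steps), giving a
# second-order accepted solution and an embedded error estimate. Backward
# Euler is A-stable, which the phospho-relay needs: its fast reactions relax
# in ~10 ms while adaptation transients run for hours.

num_jacobian <- function(f, y, eps = 1e-7) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(y[j]), 1)
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- ym[j] - h
    J[, j] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}

# one backward-Euler step by Newton iteration
be_step <- function(f, y, h, J = NULL, newton_tol = 1e-12, max_newton = 20) {
  n <- length(y)
  if (is.null(J)) J <- num_jacobian(f, y)
  A <- diag(n) - h * J
  z <- y
  for (it in seq_len(max_newton)) {
    g <- z - y - h * f(z)
    dz <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(dz)) return(NULL)
    z <- z - dz
    if (max(abs(dz)) < newton_tol * max(1, max(abs(z)))) break
  }
  z
}

#' Integrate a (possibly stiff) ODE system
#'
#' Adaptive semi-implicit integrator used by the pathway model. Returns the
#' state at each requested output time.
#'
#' @param f Derivative function `f(y)` returning `dy/dt`.
#' @param y0 Initial state.
#' @param times Output times (increasing, first is the initial time).
#' @param rtol,atol Relative/absolute error tolerances per step.
#' @param h0 Initial step (s).
#' @param hmax Maximum step (s).
#' @return Matrix with `length(times)` rows (one per output time).
#' @export
ode_integrate <- function(f, y0, times, rtol = 1e-8, atol = 1e-10,
                          h0 = 1e-3, hmax = Inf) {
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  h <- h0
  for (k in 2:length(times)) {
    tk <- times[k]
    while (t < tk - 1e-12 * max(1, abs(tk))) {
      h <- min(h, tk - t, hmax)
      J <- num_jacobian(f, y)
      yA <- be_step(f, y, h, J)
      yH <- be_step(f, y, h / 2, J)
      yB <- if (!is.null(yH)) be_step(f, yH, h / 2) else NULL
      if (is.null(yA) || is.null(yB)) { h <- h / 4; next }
      err <- max(abs(yB - yA) / (atol + rtol * pmax(abs(yB), abs(y))))
      if (is.finite(err) && err <= 1) {
        y <- 2 * yB - yA            # Richardson extrapolation, order 2
        t <- t + h
        h <- h * min(4, max(0.5, 0.9 / sqrt(max(err, 1e-10))))
      } else {
        h <- h / 2
        if (h < 1e-12) stop("ode_integrate: step size underflow")
      }
    }
    out[k, ] <- y
  }
  out
}
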