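#' Flagellar motor switching parameters
#'
#' Two-state (CW/CCW) flagellar motor whose switching rates depend on the
#' intracellular CheY-P concentration through a logistic free-energy model:
#' \deqn{k_\pm = \epsilon \exp\{\pm [\,g/2\,(1/2 - Y_p/(Y_p+K_D))\,]\}}
#' The sign convention is chosen so that the clockwise (tumble-inducing) rate
#' increases with CheY-P, matching the biology of CheY-P binding to FliM.
#'
#' @param epsilon Base switching rate (1/s).
#' @param g Dimensionless free-energy gain of the switch.
#' @param K_D CheY-P dissociation constant at the motor (uM).
#' @return An object of class `motor_params`.
#' @examples
#' mp <- motor_params()
#' motor_switch_rates(3.06, mp)  # symmetric at Yp = K_D
#' @export
motor_params <- function(epsilon = 1.3, g = 40, K_D = 3.06) {
  stopifnot(is.numeric(epsilon), epsilon > 0,
            is.numeric(g), g > 0,
            is.numeric(K_D), K_D > 0)
  structure(list(epsilon = epsilon, g = g, K_D = K_D), class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat(sprintf("<motor_params> epsilon = %g 1/s, g = %g, K_D = %g uM\n",
              x$epsilon, x$g, x$K_D))
  invisible(x)
}

#' CW/CCW motor switching rates at a given CheY-P level
#'
#' @param Yp CheY-P concentration (uM), non-negative; vectorized.
#' @param mp A [motor_params()] object.
#' @return A list with components `k_to_CW` (CCW->CW rate) and `k_to_CCW`
#'   (CW->CCW rate), both in 1/s. Their product equals `epsilon^2` for every
#'   `Yp`.
#' @export
motor_switch_rates <- function(Yp, mp = motor_params()) {
  stopifnot(inherits(mp, "motor_params"))
  if (any(!is.finite(Yp)) || any(Yp < 0))
    stop("Yp must be finite and non-negative")
  u <- mp$g / 2 * (0.5 - Yp / (Yp + mp$K_D))
  # CW rate rises with Yp (u decreases with Yp), hence exp(-u)
  list(k_to_CW = mp$epsilon * exp(-u), k_to_CCW = mp$epsilon * exp(u))
}

#' Steady-state clockwise bias of a single flagellar motor
#'
#' Stationary probability of the CW state of the two-state switch,
#' `k_CW / (k_CW + k_CCW)`, a logistic function of the motor free energy.
#'
#' @inheritParams motor_switch_rates
#' @return Probability in \[0, 1\], monotone non-decreasing in `Yp`.
#' @export
single_motor_cw_bias <- function(Yp, mp = motor_params()) {
  k <- motor_switch_rates(Yp, mp)
  k$k_to_CW / (k$k_to_CW + k$k_to_CCW)
}

#' Theoretical tumble bias of a cell
#'
#' Maps the single-motor CW bias to the fraction of time the cell tumbles.
#' With one flagellum the two coincide. For `n_flagella > 1` the only
#' supported coordination rule is the independent-motor "any motor CW implies
#' tumble" approximation: `TB = 1 - (1 - b)^n`. Exact multi-flagella
#' coordination (veto/voting models) is out of scope.
#'
#' @inheritParams motor_switch_rates
#' @param n_flagella Number of independent motors (integer >= 1).
#' @param rule Coordination rule; `"single"` (default, uses only one motor)
#'   or `"any_cw"` (tumble when any of the `n_flagella` motors is CW).
#' @return Tumble-bias probability in \[0, 1\].
#' @export
tumble_bias_theoretical <- function(Yp, mp = motor_params(), n_flagella = 1L,
                                    rule = c("single", "any_cw")) {
  rule <- match.arg(rule)
  stopifnot(n_flagella >= 1)
  b <- single_motor_cw_bias(Yp, mp)
  if (rule == "single" || n_flagella == 1L) return(b)
  1 - (1 - b)^n_flagella
}
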