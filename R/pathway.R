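# Chemotaxis signaling model in the absence of stimuli, extended with
# CheB-dependent receptor deamidation. State (all uM):
#   Q   glutamine residues on receptors (unmodifiable until deamidated)
#   M   methylated glutamate residues
#   A_P, B_P, Y_P  phosphorylated CheA, CheB, CheY
# Receptors are synthesized in the QEQE configuration (2 glutamines of 4
# methylation sites); CheB-P irreversibly deamidates Q -> E so that sites
# become available for reversible (de)methylation. Receptor-cluster activity
# is an MWC logistic in the per-site methylated and glutamine fractions.

MOLEC_PER_UM_FL <- 602.214076  # molecules per (uM * fL)

#' Pathway parameters
#'
#' All concentrations in uM, rates in 1/s or 1/(uM s). Copy numbers are
#' converted through the configurable cell `volume`. Defaults are a
#' documented self-consistent set assembled from the antecedent pathway
#' models and measured copy numbers (CheA 6700, CheB 240, CheY 8200, CheZ
#' 3200, CheR 140, ~15000 receptor monomers per cell). The methylation cycle
#' operates with a saturated (receptor-tethered) CheR and first-order CheB
#' kinetics (`K_R` small, `K_B` large); the methods vignette derives why the
#' CheB-deamidation asymmetry requires this regime and documents the one-off
#' calibration of the free-energy offset and motor readout against the
#' wild-type tumble bias. Every value can be overridden.
#'
#' @param counts Optional named list/vector of per-cell molecule counts to
#'   override (`CheR`, `CheB`, `CheA`, `CheY`, `CheZ`, `T`); converted to
#'   concentrations through `volume`.
#' @param volume Cell volume (fL) for number <-> concentration conversion.
#' @param k_R,k_B,k_Q Methylation, demethylation and deamidation catalytic
#'   rates (1/s); default `k_Q = k_B/2` (deamidation half the demethylation
#'   rate).
#' @param K_R,K_B Michaelis-Menten constants of CheR/CheB receptor binding
#'   (uM).
#' @param a_P Receptor-coupled CheA autophosphorylation rate (1/s, scaled by
#'   activity).
#' @param a_B,a_Y Phosphotransfer rates to CheB and CheY (1/(uM s)).
#' @param d_B CheB-P auto-dephosphorylation rate (1/s).
#' @param d_Z CheZ-mediated CheY-P dephosphorylation rate (1/(uM s)).
#' @param chez_mult Scalar multiplier on the CheZ concentration (a
#'   calibration knob for the wild-type operating point; default 1).
#' @param eps0,eps1,eps2 MWC free-energy constants (kT); `eps2` defaults to
#'   `eps1/2` (a glutamine contributes half the free-energy change of a
#'   methylated glutamate).
#' @param N MWC receptor-complex size.
#' @param r Cell growth rate (1/s); default `log(2)/3600` (doubling time
#'   1 h).
#' @param CheA_Tot,CheB_Tot,CheY_Tot,CheZ,CheR,T_Tot Concentrations (uM);
#'   defaults derive from the copy numbers above.
#' @param deamidation Logical; `FALSE` freezes Q at 0 (the ablated,
#'   ratio-only model).
#' @return An object of class `pathway_params`.
#' @export
pathway_params <- function(counts = NULL, volume = 1.4,
                           k_R = 0.03, k_B = 0.6, k_Q = k_B / 2,
                           K_R = 2, K_B = 40,
                           a_P = 50, a_B = 100, a_Y = 100,
                           d_B = 1, d_Z = 14, chez_mult = 1,
                           eps0 = 1.7, eps1 = -1, eps2 = eps1 / 2,
                           N = 6, r = log(2) / 3600,
                           CheA_Tot = NULL, CheB_Tot = NULL,
                           CheY_Tot = NULL, CheZ = NULL,
                           CheR = NULL, T_Tot = NULL,
                           deamidation = TRUE) {
  omega <- MOLEC_PER_UM_FL * volume
  def_counts <- c(CheA = 6700, CheB = 240, CheY = 8200, CheZ = 3200,
                  CheR = 140, T = 15000)
  if (!is.null(counts)) {
    counts <- unlist(counts)
    bad <- setdiff(names(counts), names(def_counts))
    if (length(bad)) stop("unknown protein counts: ",
                          paste(bad, collapse = ", "))
    def_counts[names(counts)] <- counts
  }
  cc <- def_counts / omega
  p <- list(
    k_R = k_R, k_B = k_B, k_Q = k_Q, K_R = K_R, K_B = K_B,
    a_P = a_P, a_B = a_B, a_Y = a_Y, d_B = d_B, d_Z = d_Z,
    chez_mult = chez_mult,
    eps0 = eps0, eps1 = eps1, eps2 = eps2, N = as.integer(N), r = r,
    CheA_Tot = if (is.null(CheA_Tot)) cc[["CheA"]] else CheA_Tot,
    CheB_Tot = if (is.null(CheB_Tot)) cc[["CheB"]] else CheB_Tot,
    CheY_Tot = if (is.null(CheY_Tot)) cc[["CheY"]] else CheY_Tot,
    CheZ = if (is.null(CheZ)) cc[["CheZ"]] else CheZ,
    CheR = if (is.null(CheR)) cc[["CheR"]] else CheR,
    T_Tot = if (is.null(T_Tot)) cc[["T"]] else T_Tot,
    volume = volume, omega = omega, deamidation = isTRUE(deamidation))
  with(p, stopifnot(k_R >= 0, k_B >= 0, k_Q >= 0, K_R > 0, K_B > 0,
                    a_P >= 0, a_B >= 0, a_Y >= 0, d_B >= 0, d_Z >= 0,
                    N >= 1, r >= 0, CheA_Tot >= 0, CheB_Tot >= 0,
                    CheY_Tot >= 0, CheZ >= 0, CheR >= 0, T_Tot > 0))
  structure(p, class = "pathway_params")
}

#' @export
print.pathway_params <- function(x, ...) {
  cat(sprintf(paste0("<pathway_params> T_Tot = %.2f uM, CheR = %.3f uM, ",
                     "CheB = %.3f uM, r = %.3g 1/s, deamidation: %s\n"),
              x$T_Tot, x$CheR, x$CheB_Tot, x$r, x$deamidation))
  invisible(x)
}

#' MWC receptor-cluster activity
#'
#' Activity in the absence of stimuli as a logistic function of the per-site
#' methylated and glutamine fractions:
#' \deqn{a = \left(1 + \exp\left[\epsilon_0 + 2N\left(\epsilon_1
#'   \frac{M}{4 T_{Tot}} + \epsilon_2 \frac{Q}{4 T_{Tot}}\right)\right]
#'   \right)^{-1}.}
#' With `eps2 = eps1/2`, one methylated site contributes the same free
#' energy as two glutamines.
#'
#' @param M Methylated glutamate concentration (uM).
#' @param Q Glutamine concentration (uM).
#' @param p A [pathway_params()].
#' @return Activity in (0, 1); vectorized over `M`, `Q`.
#' @export
receptor_activity <- function(M, Q, p) {
  if (any(M < 0) || any(Q < 0)) stop("M and Q must be non-negative")
  if (any(M + Q > 4 * p$T_Tot * (1 + 1e-9)))
    stop("M + Q exceeds the 4 methylation sites per receptor")
  E <- p$eps0 + 2 * p$N * (p$eps1 * M / (4 * p$T_Tot) +
                             p$eps2 * Q / (4 * p$T_Tot))
  1 / (1 + exp(E))
}

#' Time derivatives of the pathway state
#'
#' State order: `(Q, M, A_P, B_P, Y_P)` in uM. Implements the deamidation
#' equation, the modified (de)methylation balance restricted to deamidated
#' sites, and the phospho-relay, with activity recomputed from `(M, Q)` at
#' every evaluation:
#' \deqn{dQ/dt = -a k_Q B_P Q/(K_B+Q) + 2 r T_{Tot} - r Q}
#' \deqn{dM/dt = (1-a) k_R R \frac{4T-M-Q}{K_R+4T-M-Q}
#'              - a k_B B_P \frac{M}{K_B+M} - r M}
#'
#' @param state Numeric vector `c(Q, M, A_P, B_P, Y_P)`.
#' @param p A [pathway_params()].
#' @return Numeric vector of the five derivatives (uM/s).
#' @export
pathway_derivatives <- function(state, p) {
  Q <- state[1]; M <- state[2]; AP <- state[3]; BP <- state[4]
  YP <- state[5]
  a <- receptor_activity(max(M, 0), max(Q, 0), p)
  Z <- p$CheZ * p$chez_mult
  free_sites <- 4 * p$T_Tot - M - Q
  dQ <- if (p$deamidation)
    -a * p$k_Q * BP * Q / (p$K_B + Q) + 2 * p$r * p$T_Tot - p$r * Q
  else 0
  dM <- (1 - a) * p$k_R * p$CheR * free_sites / (p$K_R + free_sites) -
    a * p$k_B * BP * M / (p$K_B + M) - p$r * M
  dAP <- a * p$a_P * (p$CheA_Tot - AP) -
    p$a_B * AP * (p$CheB_Tot - BP) - p$a_Y * AP * (p$CheY_Tot - YP)
  dBP <- p$a_B * AP * (p$CheB_Tot - BP) - p$d_B * BP
  dYP <- p$a_Y * AP * (p$CheY_Tot - YP) - p$d_Z * Z * YP
  c(dQ, dM, dAP, dBP, dYP)
}

# QEQE synthesis state: two glutamines per receptor, nothing methylated or
# phosphorylated
qeqe_state <- function(p) c(Q = if (p$deamidation) 2 * p$T_Tot else 0,
                            M = 0, A_P = 0, B_P = 0, Y_P = 0)

# Fast approximate steady state by nested fixed point: given an activity a,
# the phospho-relay quasi-steady state is a 1-D root in A_P (B_P and Y_P are
# closed forms of A_P), steady Q is the positive root of a quadratic, and
# steady M a monotone 1-D root. Iterating on a converges in a few dozen
# cheap steps and provides the Newton starting point.
fixed_point_guess <- function(p, max_iter = 200, tol = 1e-10) {
  a <- 0.3
  Z <- p$CheZ * p$chez_mult
  phospho <- function(a) {
    BP_of <- function(AP) p$CheB_Tot * p$a_B * AP / (p$a_B * AP + p$d_B)
    YP_of <- function(AP) {
      if (p$d_Z * Z + p$a_Y < 1e-300) return(p$CheY_Tot)
      p$CheY_Tot * p$a_Y * AP / (p$a_Y * AP + p$d_Z * Z)
    }
    g <- function(AP)
      a * p$a_P * (p$CheA_Tot - AP) -
        p$a_B * AP * (p$CheB_Tot - BP_of(AP)) -
        p$a_Y * AP * (p$CheY_Tot - YP_of(AP))
    if (a <= 0 || p$CheA_Tot <= 0) {
      AP <- 0
    } else if (g(p$CheA_Tot * (1 - 1e-12)) > 0) {
      AP <- p$CheA_Tot
    } else {
      AP <- stats::uniroot(g, c(0, p$CheA_Tot), tol = 1e-14)$root
    }
    c(AP = unname(AP), BP = unname(BP_of(AP)), YP = unname(YP_of(AP)))
  }
  for (it in seq_len(max_iter)) {
    ph <- phospho(a)
    BP <- ph[["BP"]]
    # steady Q: r Q^2 + (a kQ BP - 2 r T + r KB) Q - 2 r T KB = 0
    Q <- if (!p$deamidation || p$r == 0) 0 else {
      bq <- a * p$k_Q * BP - 2 * p$r * p$T_Tot + p$r * p$K_B
      cq <- -2 * p$r * p$T_Tot * p$K_B
      (-bq + sqrt(bq^2 - 4 * p$r * cq)) / (2 * p$r)
    }
    Q <- min(Q, 4 * p$T_Tot)
    hM <- function(M) {
      f <- 4 * p$T_Tot - M - Q
      (1 - receptor_activity(M, Q, p)) * p$k_R * p$CheR * f / (p$K_R + f) -
        receptor_activity(M, Q, p) * p$k_B * BP * M / (p$K_B + M) - p$r * M
    }
    Mmax <- 4 * p$T_Tot - Q
    M <- if (hM(0) <= 0) 0
    else if (hM(Mmax * (1 - 1e-12)) >= 0) Mmax
    else stats::uniroot(hM, c(0, Mmax * (1 - 1e-12)), tol = 1e-13)$root
    a_new <- receptor_activity(M, Q, p)
    if (abs(a_new - a) < tol) { a <- a_new; break }
    a <- (a + a_new) / 2
  }
  ph <- phospho(a)
  c(Q = unname(Q), M = unname(M), A_P = unname(ph[["AP"]]),
    B_P = unname(ph[["BP"]]), Y_P = unname(ph[["YP"]]))
}

project_state <- function(y, p) {
  y[1] <- min(max(y[1], 0), 4 * p$T_Tot)
  y[2] <- min(max(y[2], 0), 4 * p$T_Tot - y[1])
  y[3] <- min(max(y[3], 0), p$CheA_Tot)
  y[4] <- min(max(y[4], 0), p$CheB_Tot)
  y[5] <- min(max(y[5], 0), p$CheY_Tot)
  if (!p$deamidation) y[1] <- 0
  y
}

#' Steady state of the pathway
#'
#' Damped Newton iteration from `guess` (default: the QEQE synthesis state
#' pre-relaxed by a short integration), with fallback to long-time
#' integration. The returned state has all five derivatives below `tol` in
#' relative units and is checked for linear stability (all Jacobian
#' eigenvalues with negative real part).
#'
#' @param p A [pathway_params()].
#' @param guess Optional initial state `c(Q, M, A_P, B_P, Y_P)`.
#' @param tol Relative residual tolerance.
#' @return A list of class `cell_state`: `state` (named vector), `activity`,
#'   `stable` (logical), `residual`, `jacobian`.
#' @export
steady_state <- function(p, guess = NULL, tol = 1e-10) {
  f <- function(y) pathway_derivatives(y, p)
  # Q is frozen at 0 when deamidation is disabled: solve on the active
  # subspace so the Jacobian stays non-singular
  act <- if (p$deamidation) 1:5 else 2:5
  scale0 <- c(p$T_Tot, p$T_Tot, max(p$CheA_Tot, 1e-6),
              max(p$CheB_Tot, 1e-6), max(p$CheY_Tot, 1e-6))
  resid <- function(y) max(abs(f(y)[act]) / scale0[act])
  newton <- function(y, iters = 100) {
    for (i in seq_len(iters)) {
      fy <- f(y)[act]
      if (max(abs(fy) / scale0[act]) < tol) break
      J <- num_jacobian(f, y)[act, act, drop = FALSE]
      dy <- tryCatch(solve(J, -fy), error = function(e) NULL)
      if (is.null(dy)) return(NULL)
      lam <- 1
      r0 <- sum((fy / scale0[act])^2)
      repeat {
        y_new <- y
        y_new[act] <- y[act] + lam * dy
        y_new <- project_state(y_new, p)
        if (sum((f(y_new)[act] / scale0[act])^2) < r0 || lam < 1e-6) break
        lam <- lam / 2
      }
      y <- y_new
    }
    y
  }
  y0 <- if (!is.null(guess)) project_state(guess, p) else
    project_state(fixed_point_guess(p), p)
  y <- newton(y0)
  if (is.null(y) || resid(y) > tol) {
    # retry from the nested fixed point if the warm start misled Newton
    y <- newton(project_state(fixed_point_guess(p), p))
  }
  if (is.null(y) || resid(y) > tol) {
    # fallback: relax much longer, then polish
    ts <- ode_integrate(f, qeqe_state(p), c(0, 5e4), rtol = 1e-8,
                        atol = 1e-11)
    y <- newton(project_state(ts[2, ], p))
  }
  if (is.null(y) || resid(y) > tol)
    stop("steady_state: no equilibrium found (residual ",
         signif(resid(if (is.null(y)) y0 else y), 3), ")")
  J <- num_jacobian(f, y)
  ev <- eigen(J[act, act, drop = FALSE], only.values = TRUE)$values
  names(y) <- c("Q", "M", "A_P", "B_P", "Y_P")
  structure(list(state = y, activity = receptor_activity(y["M"], y["Q"], p),
                 stable = all(Re(ev) < 0), residual = resid(y),
                 jacobian = J, eigenvalues = ev),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat("<cell_state> steady state (uM):\n")
  print(round(x$state, 5))
  cat(sprintf("  activity = %.4f, stable = %s, residual = %.2g\n",
              x$activity, x$stable, x$residual))
  invisible(x)
}

#' Tumble bias from a CheY-P concentration
#'
#' Motor steady-state readout. `motor = "direct"` delegates to
#' [single_motor_cw_bias()] (the fast, non-adaptive switching curve, Hill
#' coefficient about `g/4`) plus the flagellar coordination rule of
#' [tumble_bias_theoretical()]. `motor = "adaptive"` (the default for
#' population work) uses the steady-state function of the adapting motor:
#' FliM remodeling cancels most of a sustained CheY-P change, so the
#' adapted CW-bias curve is a much shallower logistic,
#' \deqn{TB = (1 + \exp[g_{ss}(1/2 - Y_p/(Y_p + Y_{half}))])^{-1},}
#' with effective gain `g_ss` (default 9.5, i.e. ~75 percent of the fast
#' gain absorbed by adaptation) and midpoint `Yp_half` (default 4.66 uM,
#' calibrated once so that the wild-type operating point maps to the
#' observed tumble bias of about 0.2; see the methods vignette).
#'
#' @inheritParams tumble_bias_theoretical
#' @param motor `"adaptive"` (default) or `"direct"`.
#' @param g_ss Effective steady-state gain of the adapted motor.
#' @param Yp_half Midpoint of the adapted response (uM).
#' @return Tumble bias in \[0, 1\], monotone in `Yp`.
#' @export
tumble_bias_from_Yp <- function(Yp, mp = motor_params(), n_flagella = 1L,
                                rule = c("single", "any_cw"),
                                motor = c("adaptive", "direct"),
                                g_ss = 9.5, Yp_half = 4.66) {
  motor <- match.arg(motor)
  rule <- match.arg(rule)
  if (motor == "direct")
    return(tumble_bias_theoretical(Yp, mp, n_flagella, rule))
  if (any(Yp < 0)) stop("Yp must be non-negative")
  b <- 1 / (1 + exp(g_ss * (0.5 - Yp / (Yp + Yp_half))))
  if (rule == "any_cw" && n_flagella > 1L) b <- 1 - (1 - b)^n_flagella
  b
}

#' Tumble-bias adaptation transient after growth arrest
#'
#' Solves the model at steady state with the given growth rate (default
#' doubling once per hour, `r = log(2)/3600` 1/s), then sets `r = 0` and
#' integrates forward, returning the tumble-bias time course. With limiting
#' CheB the initial state carries a glutamine (Q) load that is slowly
#' deamidated, so TB starts high and decays over about an hour; with
#' abundant CheB the transient is flat.
#'
#' @param p A [pathway_params()]; its `r` is used for the initial steady
#'   state.
#' @param duration Integration time after growth arrest (s).
#' @param n_out Number of output time points.
#' @param mp,n_flagella,rule Motor readout, as in [tumble_bias_from_Yp()].
#' @param rtol Relative tolerance of the transient integration.
#' @return A data.frame: `t`, `Q`, `M`, `A_P`, `B_P`, `Y_P`, `activity`,
#'   `tumble_bias`.
#' @export
adaptation_transient <- function(p, duration = 7200, n_out = 121,
                                 mp = motor_params(), n_flagella = 1L,
                                 rule = "single", rtol = 1e-7) {
  stopifnot(duration > 0)
  ss <- steady_state(p)
  p0 <- p
  p0$r <- 0
  f <- function(y) pathway_derivatives(y, p0)
  times <- seq(0, duration, length.out = n_out)
  out <- ode_integrate(f, ss$state, times, rtol = rtol, atol = 1e-10)
  act <- receptor_activity(pmax(out[, 2], 0), pmax(out[, 1], 0), p0)
  data.frame(t = times, Q = out[, 1], M = out[, 2], A_P = out[, 3],
             B_P = out[, 4], Y_P = out[, 5], activity = act,
             tumble_bias = tumble_bias_from_Yp(pmax(out[, 5], 0), mp,
                                               n_flagella, rule))
}
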