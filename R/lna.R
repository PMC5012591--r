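# Linear noise approximation of the pathway master equation. The reaction
# list mirrors the deterministic equations term-for-term (Michaelis-Menten
# aggregates as elementary events); the stationary covariance solves the
# Lyapunov equation A C + C A^T + B^T B = 0 with B^T B = S diag(v) S^T.

#' Elementary reaction list of the pathway
#'
#' Stoichiometry matrix `S` (5 species x 11 reactions, species order
#' Q, M, A_P, B_P, Y_P) and macroscopic propensity vector `v` (uM/s)
#' evaluated at a state. By construction `S %*% v` equals
#' [pathway_derivatives()] exactly; a unit test asserts this identity.
#'
#' @param state Numeric vector `c(Q, M, A_P, B_P, Y_P)` (uM).
#' @param p A [pathway_params()].
#' @return A list with `S` and `v`.
#' @export
pathway_reactions <- function(state, p) {
  state <- unname(state)
  Q <- state[1]; M <- state[2]; AP <- state[3]; BP <- state[4]
  YP <- state[5]
  a <- receptor_activity(max(M, 0), max(Q, 0), p)
  Z <- p$CheZ * p$chez_mult
  free <- 4 * p$T_Tot - M - Q
  deam <- as.numeric(p$deamidation)
  v <- c(deamidation = deam * a * p$k_Q * BP * Q / (p$K_B + Q),
         Q_synthesis = deam * 2 * p$r * p$T_Tot,
         Q_dilution = deam * p$r * Q,
         methylation = (1 - a) * p$k_R * p$CheR * free / (p$K_R + free),
         demethylation = a * p$k_B * BP * M / (p$K_B + M),
         M_dilution = p$r * M,
         autophosphorylation = a * p$a_P * (p$CheA_Tot - AP),
         transfer_B = p$a_B * AP * (p$CheB_Tot - BP),
         transfer_Y = p$a_Y * AP * (p$CheY_Tot - YP),
         BP_dephosphorylation = p$d_B * BP,
         YP_dephosphorylation = p$d_Z * Z * YP)
  S <- matrix(0, 5, 11,
              dimnames = list(c("Q", "M", "A_P", "B_P", "Y_P"), names(v)))
  S["Q", c("deamidation", "Q_dilution")] <- -1
  S["Q", "Q_synthesis"] <- 1
  S["M", "methylation"] <- 1
  S["M", c("demethylation", "M_dilution")] <- -1
  S["A_P", "autophosphorylation"] <- 1
  S["A_P", c("transfer_B", "transfer_Y")] <- -1
  S["B_P", "transfer_B"] <- 1
  S["B_P", "BP_dephosphorylation"] <- -1
  S["Y_P", "transfer_Y"] <- 1
  S["Y_P", "YP_dephosphorylation"] <- -1
  list(S = S, v = v)
}

#' Solve the continuous Lyapunov equation A C + C A' + B2 = 0
#'
#' Direct solve through the Kronecker form; adequate for the small systems
#' used here (n <= ~20).
#'
#' @param A Stable square matrix (all eigenvalues with negative real part).
#' @param B2 Symmetric diffusion matrix of the same dimension.
#' @return The symmetric solution `C`.
#' @export
solve_lyapunov <- function(A, B2) {
  n <- nrow(A)
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  C <- matrix(solve(K, -as.vector(B2)), n, n)
  (C + t(C)) / 2
}

#' Linear-noise-approximation covariance of the pathway at steady state
#'
#' Builds the reaction network in molecule numbers (through the cell
#' volume), linearizes at the steady state and solves the Lyapunov equation
#' for the stationary covariance. Also reports the slowest relaxation time
#' `tau_adapt = -1/max(Re lambda(A))` and the effective number of
#' independent CheY-P samples in an observation window,
#' `n_eff = max(1, round(T_obs/tau_adapt))`.
#'
#' @param ss A [steady_state()] result (must be stable).
#' @param p The matching [pathway_params()].
#' @param T_obs Observation window (s), default 100 (the average recorded
#'   trajectory length).
#' @return A list of class `lna_system`: `S`, `v` (molecules/s), `A`
#'   (Jacobian, 1/s), `B2`, `C` (molecule^2), `var_Yp` (uM^2), `tau_adapt`
#'   (s), `n_eff`, `T_obs`, `residual`, `species` (names of the fluctuating
#'   species kept in the solve).
#' @export
lna_covariance <- function(ss, p, T_obs = 100) {
  stopifnot(inherits(ss, "cell_state"))
  if (!ss$stable) stop("lna_covariance requires a stable steady state")
  rx <- pathway_reactions(ss$state, p)
  A_full <- ss$jacobian            # d(conc rate)/d(conc) == count Jacobian
  keep <- which(apply(abs(A_full) > 1e-14, 1, any))
  A <- A_full[keep, keep, drop = FALSE]
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0)
    stop("unstable Jacobian: leading eigenvalue ", signif(max(Re(ev)), 4))
  v_counts <- p$omega * rx$v       # events/s
  S <- rx$S[keep, , drop = FALSE]
  B2 <- S %*% diag(v_counts) %*% t(S)
  C <- solve_lyapunov(A, B2)
  resid <- max(abs(A %*% C + C %*% t(A) + B2)) / max(abs(B2))
  if (resid > 1e-8) stop("Lyapunov residual too large: ", signif(resid, 3))
  tau <- -1 / max(Re(ev))
  iy <- match("Y_P", rownames(S))
  structure(list(S = S, v = v_counts, A = A, B2 = B2, C = C,
                 var_Yp = C[iy, iy] / p$omega^2,
                 tau_adapt = tau,
                 n_eff = max(1L, as.integer(round(T_obs / tau))),
                 T_obs = T_obs, residual = resid,
                 species = rownames(S)),
            class = "lna_system")
}

#' @export
print.lna_system <- function(x, ...) {
  cat(sprintf(paste0("<lna_system> %d species, var(Y_P) = %.4g uM^2, ",
                     "tau_adapt = %.3g s, n_eff = %d\n"),
              length(x$species), x$var_Yp, x$tau_adapt, x$n_eff))
  invisible(x)
}

#' Stochastic-simulation oracle for the pathway
#'
#' Exact event-driven (Gillespie) simulation of the same reaction network in
#' molecule numbers. Returns time-weighted means and variances of the five
#' species over the sampling window. Intended as an independent check of
#' [lna_covariance()]; population work never uses it.
#'
#' @param ss Initial [steady_state()] (simulation starts at the rounded
#'   steady-state counts).
#' @param p A [pathway_params()].
#' @param t_burnin Discarded equilibration time (s).
#' @param t_sample Sampling window (s).
#' @param max_events Event budget safeguard.
#' @param seed RNG seed.
#' @return A list: `mean`, `var` (counts and counts^2), `var_Yp_conc`
#'   (uM^2), `events`, `t_final`.
#' @export
ssa_pathway <- function(ss, p, t_burnin = 500, t_sample = 4000,
                        max_events = 5e9, seed = 1L) {
  n0 <- round(ss$state * p$omega)
  pars <- c(p$k_Q, p$k_R, p$k_B, p$K_R, p$K_B, p$a_P, p$a_B, p$a_Y,
            p$d_B, p$d_Z, p$eps0, p$eps1, p$eps2, p$N, p$r,
            p$CheA_Tot, p$CheB_Tot, p$CheY_Tot, p$CheZ * p$chez_mult,
            p$CheR, p$T_Tot, p$omega, as.numeric(p$deamidation))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- ssa_pathway_cpp(as.numeric(n0), pars, t_burnin, t_sample,
                         max_events)
  out$var_Yp_conc <- out$var[["Y_P"]] / p$omega^2
  out
}
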