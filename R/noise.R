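# Correlated lognormal protein-number sampling (intrinsic + extrinsic
# noise) and the slow-fluctuation effective CheY-P machinery.

#' Expression-noise specification
#'
#' Protein numbers are sampled per cell as
#' `ln N = ln(mean) + eta_ext * z_operon + eta_int * z_protein`,
#' with one shared standard-normal extrinsic deviate per operon group and
#' independent intrinsic deviates per protein (eta are ln-space SDs).
#' Defaults: `eta_ext = 0.26` and `eta_int = 0.125` for CheR and CheB; the
#' same shapes reduced to a tenth for all other chemotaxis proteins. Operon
#' groups follow the E. coli gene organization: `mocha` (CheA) and `meche`
#' (receptors, CheR, CheB, CheY, CheZ).
#'
#' @param means Named mean copy numbers per protein.
#' @param eta_int,eta_ext Named ln-space noise SDs per protein.
#' @param operon_groups Named list of protein sets sharing one extrinsic
#'   deviate.
#' @param reduction Factor applied to the non-CheR/CheB noise (default 0.1).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(means = c(CheR = 140, CheB = 240, CheA = 6700,
                                 CheY = 8200, CheZ = 3200, T = 15000),
                       eta_int = NULL, eta_ext = NULL,
                       operon_groups = list(
                         mocha = "CheA",
                         meche = c("T", "CheR", "CheB", "CheY", "CheZ")),
                       reduction = 0.1) {
  prot <- names(means)
  if (is.null(eta_int)) {
    eta_int <- ifelse(prot %in% c("CheR", "CheB"), 0.125, 0.125 * reduction)
    names(eta_int) <- prot
  }
  if (is.null(eta_ext)) {
    eta_ext <- ifelse(prot %in% c("CheR", "CheB"), 0.26, 0.26 * reduction)
    names(eta_ext) <- prot
  }
  stopifnot(all(means > 0), all(eta_int >= 0), all(eta_ext >= 0),
            all(unlist(operon_groups) %in% prot))
  structure(list(means = means, eta_int = eta_int, eta_ext = eta_ext,
                 operon_groups = operon_groups, reduction = reduction),
            class = "noise_spec")
}

#' Sample per-cell protein numbers
#'
#' @param spec A [noise_spec()].
#' @param n_cells Number of cells.
#' @param seed RNG seed.
#' @return A numeric matrix (`n_cells` x proteins) of copy numbers.
#' @export
sample_protein_numbers <- function(spec, n_cells, seed = 1L) {
  stopifnot(inherits(spec, "noise_spec"), n_cells >= 1)
  prot <- names(spec$means)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  zext <- matrix(stats::rnorm(n_cells * length(spec$operon_groups)),
                 n_cells, length(spec$operon_groups),
                 dimnames = list(NULL, names(spec$operon_groups)))
  out <- matrix(0, n_cells, length(prot), dimnames = list(NULL, prot))
  group_of <- rep(NA_character_, length(prot))
  names(group_of) <- prot
  for (g in names(spec$operon_groups))
    group_of[spec$operon_groups[[g]]] <- g
  for (pr in prot) {
    ze <- if (is.na(group_of[pr])) stats::rnorm(n_cells) else zext[, group_of[pr]]
    zi <- stats::rnorm(n_cells)
    out[, pr] <- exp(log(spec$means[pr]) + spec$eta_ext[pr] * ze +
                       spec$eta_int[pr] * zi)
  }
  out
}

#' Effective CheY-P over an observation window
#'
#' The receptor-cluster activity fluctuates on the adaptation timescale, so
#' a tumble-bias measurement over `T_obs` seconds averages roughly
#' `n_eff = T_obs/tau_adapt` independent CheY-P levels. Returns the mean of
#' `n_eff` Gaussian draws centered at the steady state (equivalently one
#' draw with variance `varYp/n_eff`), clipped at 0.
#'
#' @param Yp_ss Steady-state CheY-P (uM); vectorized.
#' @param varYp LNA variance of CheY-P (uM^2); recycled.
#' @param n_eff Effective sample count (from [lna_covariance()]); recycled.
#' @param seed Optional seed (NULL inherits the caller's RNG stream).
#' @return A list: `Yp` (draws) and `n_clipped`.
#' @export
effective_Yp <- function(Yp_ss, varYp, n_eff, seed = NULL) {
  stopifnot(all(varYp >= 0), all(n_eff >= 1))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  draw <- stats::rnorm(length(Yp_ss), mean = Yp_ss,
                       sd = sqrt(varYp / n_eff))
  n_clipped <- sum(draw < 0)
  list(Yp = pmax(draw, 0), n_clipped = n_clipped)
}

#' Simulate a population phenotype panel
#'
#' Per cell: sample protein numbers, solve the pathway steady state,
#' optionally add slow-fluctuation noise through the LNA (`with_lna`), and
#' read out tumble bias through the motor model. `with_lna = FALSE`
#' reproduces the no-signaling-noise ablation.
#'
#' @param spec A [noise_spec()]; used when `sampling = "lognormal"`.
#' @param p Baseline [pathway_params()] (copy-number fields are overridden
#'   per cell).
#' @param n_cells Number of cells.
#' @param seed RNG seed (drives sampling and the effective-CheY-P draws).
#' @param with_lna Add receptor-cluster signaling noise?
#' @param sampling `"lognormal"` (wild-type-like, via `spec`) or
#'   `"loguniform"` (independent log-uniform CheR and CheB spanning
#'   `range_R` / `range_B`, emulating the induction panels that cover the
#'   full phenotype range; other proteins at their means).
#' @param range_R,range_B Copy-number ranges for `"loguniform"` sampling.
#' @param T_obs Observation window for `n_eff` (s).
#' @param mp,n_flagella,rule Motor readout.
#' @return A data.frame of class `population_sample`: per-cell copy numbers,
#'   `Yp_ss`, `var_Yp`, `tau_adapt`, `n_eff`, `Yp_eff`, `tumble_bias`, plus
#'   attributes `seed` and `n_failed` (solver failures, excluded).
#' @export
simulate_population_phenotypes <- function(spec = noise_spec(),
                                           p = pathway_params(),
                                           n_cells = 1000, seed = 1L,
                                           with_lna = TRUE,
                                           sampling = c("lognormal",
                                                        "loguniform"),
                                           range_R = c(10, 20000),
                                           range_B = c(10, 20000),
                                           T_obs = 100,
                                           mp = motor_params(),
                                           n_flagella = 1L,
                                           rule = "single") {
  sampling <- match.arg(sampling)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  if (sampling == "lognormal") {
    counts <- sample_protein_numbers(spec, n_cells, seed)
  } else {
    # induction-panel emulation: CheR and CheB scan their ranges
    # log-uniformly; the other proteins keep their natural (reduced)
    # expression noise, as in the population simulations of the study
    counts <- sample_protein_numbers(spec, n_cells, seed)
    set.seed(cell_seed(seed, 555L))
    counts[, "CheR"] <- exp(stats::runif(n_cells, log(range_R[1]),
                                         log(range_R[2])))
    counts[, "CheB"] <- exp(stats::runif(n_cells, log(range_B[1]),
                                         log(range_B[2])))
  }
  set.seed(cell_seed(seed, 777L))  # stream for the effective-Yp draws
  nprot <- colnames(counts)
  res <- vector("list", n_cells)
  guess <- NULL
  n_failed <- 0L
  for (i in seq_len(n_cells)) {
    pi <- p
    cnt <- function(nm) unname(counts[i, nm]) / p$omega
    pi$CheR <- cnt("CheR")
    pi$CheB_Tot <- cnt("CheB")
    if ("CheA" %in% nprot) pi$CheA_Tot <- cnt("CheA")
    if ("CheY" %in% nprot) pi$CheY_Tot <- cnt("CheY")
    if ("CheZ" %in% nprot) pi$CheZ <- cnt("CheZ")
    if ("T" %in% nprot) pi$T_Tot <- cnt("T")
    ss <- tryCatch(steady_state(pi, guess = guess),
                   error = function(e) NULL)
    if (is.null(ss)) ss <- tryCatch(steady_state(pi),
                                    error = function(e) NULL)
    if (is.null(ss) || !ss$stable) { n_failed <- n_failed + 1L; next }
    guess <- ss$state
    yp <- unname(ss$state["Y_P"])
    var_yp <- NA_real_; tau <- NA_real_; neff <- NA_integer_
    yp_eff <- yp
    if (with_lna) {
      sys <- tryCatch(lna_covariance(ss, pi, T_obs = T_obs),
                      error = function(e) NULL)
      if (is.null(sys)) { n_failed <- n_failed + 1L; next }
      var_yp <- sys$var_Yp; tau <- sys$tau_adapt; neff <- sys$n_eff
      yp_eff <- effective_Yp(yp, var_yp, neff)$Yp
    }
    res[[i]] <- data.frame(
      cell_id = sprintf("cell_%05d", i),
      N_R = counts[i, "CheR"], N_B = counts[i, "CheB"],
      Yp_ss = yp, var_Yp = var_yp, tau_adapt = tau, n_eff = neff,
      Yp_eff = yp_eff,
      tumble_bias = tumble_bias_from_Yp(yp_eff, mp, n_flagella, rule),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "seed") <- seed
  attr(out, "n_failed") <- n_failed
  class(out) <- c("population_sample", "data.frame")
  out
}

#' Fraction of phenotype variance explained by CheR/CheB expression noise
#'
#' Pushes sampled wild-type (N_R, N_B) pairs through a tumble-bias surface
#' and ratios the resulting variance against the observed population
#' variance.
#'
#' @param tb_surface A function `f(N_R, N_B) -> TB` or a `phenotype_map`
#'   (queried by bilinear interpolation; points outside the support are
#'   flagged).
#' @param spec A [noise_spec()].
#' @param observed_var Observed tumble-bias variance (default `0.093^2`,
#'   the wild-type population SD).
#' @param n_cells Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return A list: `fraction`, `var_model`, `observed_var`, `n_outside`.
#' @export
variance_explained <- function(tb_surface, spec = noise_spec(),
                               observed_var = 0.093^2, n_cells = 100000,
                               seed = 1L) {
  counts <- sample_protein_numbers(spec, n_cells, seed)
  if (inherits(tb_surface, "phenotype_map")) {
    tb <- predict(tb_surface, counts[, "CheR"], counts[, "CheB"])
    n_outside <- sum(is.na(tb))
    if (n_outside > 0.05 * n_cells)
      warning(sprintf("%d of %d sampled cells outside the map support",
                      n_outside, n_cells))
    tb <- tb[!is.na(tb)]
  } else {
    tb <- tb_surface(counts[, "CheR"], counts[, "CheB"])
    n_outside <- 0L
  }
  list(fraction = stats::var(tb) / observed_var,
       var_model = stats::var(tb), observed_var = observed_var,
       n_outside = n_outside)
}
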