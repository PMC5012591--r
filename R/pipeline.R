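# End-to-end orchestration: simulate -> classify -> diffuse -> merge with
# true protein numbers -> map. All randomness flows from one root seed.

#' Run configuration
#'
#' Flat key-value configuration with documented defaults; unknown keys are
#' rejected.
#'
#' @param seed Root RNG seed.
#' @param n_cells Number of simulated cells.
#' @param duration Trajectory duration (s).
#' @param out_dir Output directory.
#' @param ... Overrides for any of the documented keys (`speed`, `D_rot`,
#'   `depth`, `dt_sample`, `dt_internal`, `n_flagella`, `epsilon`, `g`,
#'   `K_D`, `min_duration`, `tol`, `bandwidth`, `with_lna`, `verbosity`).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_cells = 100, duration = 120,
                       out_dir = tempfile("motilitymap_run_"), ...) {
  cfg <- list(seed = as.integer(seed), n_cells = n_cells,
              duration = duration, out_dir = out_dir,
              speed = 20, D_rot = 0.062, depth = 10, dt_sample = 0.1,
              dt_internal = 0.01, n_flagella = 1L,
              epsilon = 1.3, g = 40, K_D = 3.06,
              min_duration = 10, tol = 0.01, bandwidth = 0.20,
              with_lna = TRUE, verbosity = 1)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full in-silico pipeline
#'
#' Samples per-cell protein numbers, solves the pathway for each cell's
#' CheY-P, simulates trajectories, classifies tumbles, fits diffusion,
#' merges the estimates with the true protein numbers, and builds the
#' phenotype maps. Writes every intermediate table to `out_dir` and returns
#' a manifest sufficient to reproduce the run.
#'
#' @param config A [run_config()].
#' @return A list of class `run_manifest`: `config`, `tables` (paths),
#'   `n_cells_processed`, counts of dropped/failed cells, and the session
#'   package version.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbosity > 0) message(sprintf(...))
  mp <- motor_params(config$epsilon, config$g, config$K_D)
  sp <- swim_params(config$speed, config$D_rot, config$depth,
                    config$dt_sample, config$dt_internal,
                    config$n_flagella)
  tables <- list()
  if (config$n_cells == 0) {
    say("n_cells = 0: writing empty outputs")
    for (s in c("trajectory", "summary", "diffusion", "population")) {
      empty <- stats::setNames(
        as.data.frame(matrix(nrow = 0, ncol = length(table_schemas[[s]]))),
        table_schemas[[s]])
      tables[[s]] <- file.path(config$out_dir, paste0(s, ".tsv"))
      write_table_schema(empty, tables[[s]], s)
    }
    return(structure(list(config = unclass(config), tables = tables,
                          n_cells_processed = 0L, n_dropped = 0L,
                          n_failed = 0L,
                          package_version =
                            as.character(utils::packageVersion("motilitymap"))),
                     class = "run_manifest"))
  }
  say("stage 1/5: population phenotypes (%d cells)", config$n_cells)
  pop <- simulate_population_phenotypes(
    noise_spec(), pathway_params(), n_cells = config$n_cells,
    seed = config$seed, with_lna = isTRUE(config$with_lna),
    sampling = "loguniform", mp = mp,
    n_flagella = config$n_flagella,
    rule = if (config$n_flagella > 1) "any_cw" else "single")
  tables$population <- file.path(config$out_dir, "population.tsv")
  write_table_schema(pop, tables$population, "population")
  say("stage 2/5: trajectories (%g s each)", config$duration)
  trajs <- simulate_cells(pop$Yp_eff, mp, sp, duration = config$duration,
                          seed = config$seed, cell_id = pop$cell_id)
  tables$trajectory <- file.path(config$out_dir, "trajectories.tsv")
  write_table_schema(trajs, tables$trajectory, "trajectory")
  say("stage 3/5: behavioral classification")
  model <- fit_behavior_model(trajs, tol = config$tol, seed = config$seed)
  summ <- summarize_cells(trajs, model, min_duration = config$min_duration)
  tables$summary <- file.path(config$out_dir, "summary.tsv")
  write_table_schema(summ, tables$summary, "summary")
  say("stage 4/5: diffusion fits")
  diff_fit <- fit_cells_diffusion(trajs)
  tables$diffusion <- file.path(config$out_dir, "diffusion.tsv")
  write_table_schema(diff_fit, tables$diffusion, "diffusion")
  say("stage 5/5: phenotype maps")
  cells <- merge(summ, pop[, c("cell_id", "N_R", "N_B")], by = "cell_id")
  map_mean <- tryCatch(
    local_linear_mean(cells, bandwidth = config$bandwidth),
    error = function(e) NULL)
  if (!is.null(map_mean)) {
    gm <- expand.grid(logR = map_mean$grid_R, logB = map_mean$grid_B)
    gm$value <- as.vector(map_mean$value)
    gm$support <- as.vector(map_mean$support_mask)
    tables$map <- file.path(config$out_dir, "map_mean_tb.tsv")
    write_table_schema(gm, tables$map, "map")
  }
  manifest <- structure(
    list(config = unclass(config), tables = tables,
         n_cells_processed = nrow(summ),
         n_dropped = config$n_cells - nrow(summ),
         n_failed = attr(pop, "n_failed"),
         package_version =
           as.character(utils::packageVersion("motilitymap"))),
    class = "run_manifest")
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `analyze`, `diffuse`, `model`, `population`,
#' `map`, `run`. Invoke from a shell via
#' `Rscript -e 'motilitymap::main_cli()' <subcommand> [options]`.
#' Options use `--key value` pairs; `--config <file>` reads a flat
#' key-value file first (command-line flags override it).
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Invisibly, the result of the dispatched stage.
#' @export
main_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: motilitymap <simulate|analyze|diffuse|model|population|",
        "map|run> [--key value ...]\n", sep = "")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest) >= 2) {
    key <- sub("^--", "", rest[1])
    val <- rest[2]
    num <- suppressWarnings(as.numeric(val))
    opts[[key]] <- if (!is.na(num)) num else val
    rest <- rest[-(1:2)]
  }
  if (!is.null(opts$config)) {
    file_opts <- read_config(opts$config)
    opts <- utils::modifyList(file_opts, opts[names(opts) != "config"])
  }
  get_opt <- function(name, default) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }
  seed <- as.integer(get_opt("seed", 1))
  out <- get_opt("out", ".")
  switch(cmd,
    simulate = {
      yp <- get_opt("yp", NA)
      tb <- get_opt("tb", NA)
      if (is.na(yp) && !is.na(tb)) {
        mp <- motor_params()
        yp <- stats::uniroot(function(y) single_motor_cw_bias(y, mp) - tb,
                             c(1e-6, 1000))$root
      }
      if (is.na(yp)) stop("simulate: need --yp or --tb")
      n <- as.integer(get_opt("n", 10))
      trajs <- simulate_cells(rep(yp, n),
                              duration = get_opt("duration", 100),
                              seed = seed)
      write_table_schema(trajs, out, "trajectory")
      message("wrote ", out)
      invisible(trajs)
    },
    analyze = {
      trajs <- read_table_schema(get_opt("tracks", stop("need --tracks")),
                                 "trajectory")
      model <- fit_behavior_model(trajs, tol = get_opt("tol", 0.01),
                                  seed = seed)
      summ <- summarize_cells(trajs, model,
                              min_duration = get_opt("min-duration", 10))
      write_table_schema(summ, out, "summary")
      message("wrote ", out)
      invisible(summ)
    },
    diffuse = {
      trajs <- read_table_schema(get_opt("tracks", stop("need --tracks")),
                                 "trajectory")
      fits <- fit_cells_diffusion(trajs,
                                  max_lag = get_opt("max-lag", NULL))
      write_table_schema(fits, out, "diffusion")
      message("wrote ", out)
      invisible(fits)
    },
    model = {
      p <- pathway_params(counts = list(
        CheR = get_opt("cheR", 140), CheB = get_opt("cheB", 240)))
      if (identical(get_opt("mode", "steady"), "transient")) {
        tr <- adaptation_transient(p,
                                   duration = get_opt("duration", 7200))
        utils::write.table(tr, out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        message("wrote ", out)
        invisible(tr)
      } else {
        ss <- steady_state(p)
        print(ss)
        cat("tumble bias:",
            tumble_bias_from_Yp(ss$state["Y_P"]), "\n")
        invisible(ss)
      }
    },
    population = {
      pop <- simulate_population_phenotypes(
        n_cells = as.integer(get_opt("n", 1000)), seed = seed,
        with_lna = is.null(opts[["no-lna"]]))
      write_table_schema(pop, out, "population")
      message("wrote ", out)
      invisible(pop)
    },
    map = {
      cells <- utils::read.table(get_opt("cells", stop("need --cells")),
                                 header = TRUE, sep = "\t")
      m <- local_linear_mean(cells,
                             bandwidth = get_opt("bandwidth", 0.2))
      gm <- expand.grid(logR = m$grid_R, logB = m$grid_B)
      gm$value <- as.vector(m$value)
      gm$support <- as.vector(m$support_mask)
      write_table_schema(gm, out, "map")
      message("wrote ", out)
      invisible(m)
    },
    run = {
      cfg <- run_config(seed = seed,
                        n_cells = as.integer(get_opt("n", 100)),
                        duration = get_opt("duration", 120),
                        out_dir = get_opt("out", tempfile("run_")))
      invisible(run_pipeline(cfg))
    },
    stop("unknown subcommand: ", cmd))
}
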