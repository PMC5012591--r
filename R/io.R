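# Plain-text table and config I/O. All tables are tab-separated with a
# header row, full double precision, SI units (s, um, uM).

table_schemas <- list(
  trajectory = c("cell_id", "t", "x", "y", "truth_state"),
  annotation = c("cell_id", "frame", "state", "p_S", "p_I", "p_T"),
  summary = c("cell_id", "tumble_bias", "mean_run_time", "mean_speed",
              "mean_cos_turn", "n_frames", "duration"),
  diffusion = c("cell_id", "v0", "tau_persist", "omega", "D_eff",
                "fit_quality", "converged"),
  population = c("cell_id", "N_R", "N_B", "Yp_ss", "var_Yp", "tau_adapt",
                 "n_eff", "Yp_eff", "tumble_bias"),
  map = c("logR", "logB", "value", "support"))

#' Write / read the package's tabular formats
#'
#' Tab-separated text with a header row and full float precision
#' (round-trip identity). `schema` names one of: trajectory, annotation,
#' summary, diffusion, population, map.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @param schema Schema name (see Details).
#' @return `read_table_schema` returns the data.frame; `write_table_schema`
#'   returns `path` invisibly.
#' @export
write_table_schema <- function(df, path, schema) {
  cols <- table_schemas[[schema]]
  if (is.null(cols)) stop("unknown schema: ", schema)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema '", schema, "': missing columns: ",
         paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, cols]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_schema
#' @export
read_table_schema <- function(path, schema) {
  cols <- table_schemas[[schema]]
  if (is.null(cols)) stop("unknown schema: ", schema)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "",
                          colClasses = NA)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema '", schema, "': missing columns: ",
         paste(missing, collapse = ", "))
  df <- df[, cols]
  if (schema == "trajectory") class(df) <- c("trajectory", "data.frame")
  df
}

#' Write / read a flat key-value config file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numeric where possible, `TRUE`/`FALSE` as logical, everything else as
#' character. Unknown keys are rejected against `allowed` when given.
#'
#' @param config Named list.
#' @param path File path.
#' @param allowed Optional character vector of permitted keys.
#' @return `read_config` returns a named list.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, as.character(config[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path, allowed = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    k <- trimws(kv[1]); v <- trimws(kv[2])
    if (!is.null(allowed) && !(k %in% allowed))
      stop("unknown config key: ", k)
    num <- suppressWarnings(as.numeric(v))
    out[[k]] <- if (!is.na(num)) num
    else if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else v
  }
  out
}
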