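#' Load a run configuration from YAML
#'
#' A configuration names the inputs of a full analysis: the parameter table
#' CSV, an optional correlation CSV, the model selector, and the numeric
#' protocol settings. Omitted settings take the reference defaults
#' (`n = 100000`, `bootstrap = 1000`, `partitions = 30`, `level = 0.95`,
#' `seed = 1`). Validation problems are collected and reported together.
#'
#' @param path path to a YAML file with fields `params` (CSV path,
#'   required), `model` (one of `"ct"`, `"tvdt"`, `"linear-example"`;
#'   required), and optionally `corr`, `n`, `partitions`, `bootstrap`,
#'   `level`, `seed`, `out`, `scenario`.
#' @return a validated list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg, dir = dirname(path))
}

#' @rdname load_config
#' @param cfg a raw configuration list (as parsed from YAML).
#' @param dir base directory for resolving relative paths.
#' @export
validate_config <- function(cfg, dir = ".") {
  defaults <- list(n = 100000L, bootstrap = 1000L, partitions = 30L,
                   level = 0.95, seed = 1L, corr = NULL, out = ".",
                   scenario = NA_character_)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
  errs <- character(0)
  if (is.null(cfg$params)) errs <- c(errs, "missing required field 'params'")
  if (is.null(cfg$model)) errs <- c(errs, "missing required field 'model'")
  for (k in c("n", "bootstrap", "partitions")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v != round(v))
      errs <- c(errs, sprintf("field '%s' must be a positive integer", k))
  }
  if (!is.numeric(cfg$level) || cfg$level <= 0 || cfg$level >= 1)
    errs <- c(errs, "field 'level' must lie in (0, 1)")
  resolve <- function(p) if (is.null(p) || file.exists(p)) p
                         else file.path(dir, p)
  for (k in c("params", "corr")) {
    p <- resolve(cfg[[k]])
    if (!is.null(p) && !is.null(cfg[[k]])) {
      if (!file.exists(p)) errs <- c(errs, sprintf(
        "field '%s': file not found: %s", k, cfg[[k]]))
      else cfg[[k]] <- p
    }
  }
  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$n <- as.integer(cfg$n); cfg$bootstrap <- as.integer(cfg$bootstrap)
  cfg$partitions <- as.integer(cfg$partitions); cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration to YAML
#'
#' The saved file loads back to an identical configuration
#' (load -> save -> load round-trips losslessly).
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' Write an analysis report to a directory
#'
#' Deterministic file naming: a `two_stage_report` produces
#' `delta_step1.csv`, `delta_step2.csv`, `two_stage_table.csv` and
#' `report.json` (classifications, thresholds, seeds, dropped-row counts);
#' an `uncertainty_summary` produces `ua_<output>.json` and the raw output
#' sample `ua_<output>_sample.csv`.
#'
#' @param report a [run_two_stage()] or [monte_carlo_summary()] result.
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(report, "two_stage_report")) {
    paths <- file.path(dir, c("delta_step1.csv", "delta_step2.csv",
                              "two_stage_table.csv", "report.json"))
    write_delta_csv(report$step1, paths[1])
    write_delta_csv(report$step2, paths[2])
    utils::write.csv(report$table, paths[3], row.names = FALSE)
    meta <- list(
      n = report$n, partitions = report$partitions, B = report$B,
      seed = report$seed, child_seeds = as.list(report$child_seeds),
      noise_thresholds = as.list(report$thresholds),
      dropped_rows = as.list(report$dropped),
      effect_class = stats::setNames(as.list(report$table$effect_class),
                                     report$table$name))
    jsonlite::write_json(meta, paths[4], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (inherits(report, "uncertainty_summary")) {
    stem <- gsub("[^A-Za-z0-9_]+", "_", report$output_name)
    paths <- file.path(dir, c(sprintf("ua_%s.json", stem),
                              sprintf("ua_%s_sample.csv", stem)))
    meta <- report[c("output_name", "n", "n_effective", "dropped_count",
                     "mean", "median", "ci_low", "ci_high", "level",
                     "seed", "independent")]
    jsonlite::write_json(meta, paths[1], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    utils::write.csv(data.frame(value = report$values), paths[2],
                     row.names = FALSE)
  } else stop("unsupported report type")
  invisible(paths)
}

#' Resolve a built-in model selector
#'
#' Maps the model names used in configurations and on the command line to
#' row-wise model functions: `"ct"` (eradication threshold), `"tvdt"`
#' (doubling time), `"linear-example"` (the linear-Gaussian benchmark
#' output recomputed from its coefficient vector).
#'
#' @param name model selector string.
#' @param host [host_constants()] for the built-in tumor-in-host metrics.
#' @return a function `matrix -> numeric vector`.
#' @export
resolve_model <- function(name, host = host_constants()) {
  switch(name,
    "ct" = ct_model(host),
    "tvdt" = tvdt_model(host),
    "linear-example" = function(X) {
      cf <- linear_benchmark_coefficients()
      drop(X[, names(cf), drop = FALSE] %*% cf)
    },
    stop("unknown model selector: ", name))
}
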