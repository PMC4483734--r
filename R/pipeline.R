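#' Read a run configuration
#'
#' Run configs are YAML (or JSON) files; every entry is optional and falls
#' back to the pipeline defaults. Anything that affects estimates lives in
#' the config so a fit is fully reproducible from config + data; every
#' written report embeds the config hash, package version and seed.
#'
#' @param path YAML/JSON file path.
#' @return named list of options.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping")
  cfg
}

#' Hash a configuration for provenance stamps
#' @param config any serializable list.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

report_stamp <- function(config, seed = NULL) {
  list(package_version = as.character(utils::packageVersion("heatlag")),
       config_hash = config_hash(config), seed = seed)
}

#' Write a synthetic dataset and its ground truth
#'
#' Runs the generator and writes `data.csv` (the standard input format) and
#' `truth.json` (surface parameters and provenance stamp) into `out_dir`.
#'
#' @param config list with optional `synth` entries (passed to
#'   [synth_config()]) and `seed` (default 1).
#' @param out_dir output directory (created if needed).
#' @return the `synth_dataset`, invisibly.
#' @export
cmd_simulate <- function(config = list(), out_dir) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  args <- config$synth %||% list()
  if (!is.null(args$surface) && !inherits(args$surface, "truth_surface")) {
    args$surface <- do.call(truth_surface, args$surface)
  }
  if (!is.null(args$cats) && !is.data.frame(args$cats)) {
    args$cats <- as.data.frame(args$cats)
  }
  sc <- do.call(synth_config, args)
  ds <- simulate_dataset(sc, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_timeseries(ds$series, file.path(out_dir, "data.csv"))
  truth <- ds$config$surface
  truth$class <- NULL
  jsonlite::write_json(
    c(unclass(truth), report_stamp(config, seed)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(ds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the category-stratified analysis and write its reports
#'
#' Reads the input CSV, runs [run_category_analysis()], and writes
#' `rr_table.csv` (the percentile RR table), `curves.csv` (one row per
#' category x grid temperature) and `fit.json` (coefficients, SEs,
#' dispersion, deviances, MMTs, provenance stamp).
#'
#' @param config list with `data` (CSV path), optional `categories`,
#'   pipeline options, `seed`.
#' @param out_dir output directory.
#' @return the `rr_analysis`, invisibly.
#' @export
cmd_fit <- function(config, out_dir) {
  series <- read_timeseries(config$data, config$categories)
  res <- run_category_analysis(series, config$categories, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$table, file.path(out_dir, "rr_table.csv"),
                   row.names = FALSE)
  curves <- do.call(rbind, lapply(names(res$curves), function(cat) {
    cv <- res$curves[[cat]]
    data.frame(category = cat, temperature = cv$grid, rr = cv$rr,
               ci_low = cv$ci_low, ci_high = cv$ci_high)
  }))
  utils::write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
  fits <- lapply(res$fits, function(f) {
    list(coefficients = as.list(f$coefficients),
         se = as.list(sqrt(diag(f$vcov))),
         dispersion = f$dispersion, deviance = f$deviance,
         null_deviance = f$null_deviance,
         deviance_explained = deviance_explained(f))
  })
  jsonlite::write_json(
    c(list(fits = fits, mmt = as.list(res$mmt)),
      report_stamp(config, config$seed)),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(res)
}

#' Run the model-simplification procedure and write its report
#'
#' Writes `transition.json` (per-stage thresholds, QAIC, deviance
#' explained, selection) and `transition_curves.csv` (the three-panel
#' stage curves).
#'
#' @param config list with `data` (CSV path) and pipeline options.
#' @param out_dir output directory.
#' @return the `transition_report`, invisibly.
#' @export
cmd_simplify <- function(config, out_dir) {
  series <- read_timeseries(config$data, config$categories)
  rep <- run_transition(series, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- lapply(rep$stages, function(s) {
    list(thresholds = if (is.null(s$thresholds)) NULL else
           unclass(s$thresholds)[c("low", "high", "source")],
         mmt = s$mmt %||% NA,
         qaic = unname(s$stats[["qaic"]]),
         deviance_explained = unname(s$stats[["dev_expl"]]),
         dispersion = unname(s$stats[["dispersion"]]))
  })
  jsonlite::write_json(
    c(list(stages = stages, selected = rep$selected,
           criterion_equivalent = rep$criterion_equivalent),
      report_stamp(config, config$seed)),
    file.path(out_dir, "transition.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  curves <- do.call(rbind, lapply(names(rep$stages), function(nm) {
    cv <- rep$stages[[nm]]$curve
    data.frame(stage = nm, temperature = cv$grid, rr = cv$rr,
               ci_low = cv$ci_low, ci_high = cv$ci_high)
  }))
  utils::write.csv(curves, file.path(out_dir, "transition_curves.csv"),
                   row.names = FALSE)
  invisible(rep)
}

#' Run the season-specific analysis and write its reports
#'
#' Writes `seasons.json` (per-season slope, SE, CI, RR per degree) and
#' `season_curves.csv`.
#'
#' @param config list with `data` (CSV path) and pipeline options.
#' @param out_dir output directory.
#' @return the `season_analysis`, invisibly.
#' @export
cmd_seasons <- function(config, out_dir) {
  series <- read_timeseries(config$data, config$categories)
  res <- run_season_analysis(series, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    c(list(seasons = split(res$table, res$table$season)),
      report_stamp(config, config$seed)),
    file.path(out_dir, "seasons.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  curves <- do.call(rbind, lapply(names(res$curves), function(s) {
    cv <- res$curves[[s]]
    data.frame(season = s, temperature = cv$grid, rr = cv$rr,
               ci_low = cv$ci_low, ci_high = cv$ci_high)
  }))
  utils::write.csv(curves, file.path(out_dir, "season_curves.csv"),
                   row.names = FALSE)
  invisible(res)
}
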