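## Reproducible end-to-end toolchain: configuration, the ingest -> fit ->
## simulate -> report pipeline, and its run manifest.

#' Default run configuration
#'
#' All defaults follow the study settings for type 2 diabetes: K = 5
#' stages, W = 12 complication categories, a 30-occurrence code filter,
#' 1-year slices, and 5000 generated patients.
#'
#' @param events,anchors input paths (anchors defaults to the bundled
#'   type 2 diabetes anchor file).
#' @param output_dir directory for all pipeline artifacts.
#' @param K,W model dimensions.
#' @param min_count rare-code filter threshold.
#' @param granularity_years slice width.
#' @param n_patients,horizon_years simulation settings.
#' @param seed master seed; each stage derives its own stream from it.
#' @param fit a [fit_control()] list.
#' @param patterns optional list of complication patterns for the report.
#' @return a validated list of class \code{run_config}.
#' @export
run_config <- function(events = NULL, anchors = NULL, output_dir = "prognet_run",
                       K = 5, W = 12, min_count = 30, granularity_years = 1,
                       n_patients = 5000, horizon_years = 60, seed = 1,
                       fit = fit_control(), patterns = NULL) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$K) || cfg$K < 2) stop("config: K must be >= 2")
  if (is.null(cfg$W) || cfg$W < 1) stop("config: W must be >= 1")
  if (cfg$min_count < 1) stop("config: min_count must be >= 1")
  if (cfg$n_patients < 1) stop("config: n_patients must be >= 1")
  if (cfg$granularity_years <= 0) stop("config: granularity_years must be > 0")
  if (cfg$horizon_years <= 0) stop("config: horizon_years must be > 0")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the study defaults of
#' [run_config()].  The \code{fit} block maps onto [fit_control()] fields.
#'
#' @param path YAML file path.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("config: unknown key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$fit)) raw$fit <- do.call(fit_control, raw$fit)
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Ingest raw events, fit the model, simulate a cohort, and write the
#' cohort reports, each stage serialized to \code{output_dir} so a rerun
#' with \code{resume = TRUE} picks up after the last completed stage.  A
#' manifest records the package version, seeds, and input digests.
#'
#' @param config a \code{run_config} (or path to a YAML config).
#' @param resume skip stages whose artifacts already exist.
#' @return invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$output_dir, f)
  art <- list(vocabulary = path("vocabulary.txt"),
              histories = path("histories.jsonl"),
              model = path("model.json"),
              cohort = path("cohort.jsonl"),
              stage_summary = path("stage_summary.csv"),
              retro_single = path("retro_single.csv"),
              manifest = path("manifest.json"))
  if (is.null(config$events) || !file.exists(config$events)) {
    stop("config: missing input events file: ",
         if (is.null(config$events)) "(unset)" else config$events)
  }
  anchors <- if (is.null(config$anchors)) t2d_anchors() else read_anchors(config$anchors)
  seeds <- config$seed + c(fit = 1L, simulate = 2L)

  ## ingest
  if (!(resume && file.exists(art$histories) && file.exists(art$vocabulary))) {
    message("[ingest] reading ", config$events)
    ev <- read_events(config$events)
    fc <- filter_codes(ev, config$min_count)
    histories <- build_time_slices(fc$events, fc$vocabulary,
                                   config$granularity_years)
    if (length(histories) == 0) stop("ingest produced no usable patient histories")
    st <- encounter_stats(histories)
    message("[ingest] ", length(histories), " patients, ", st$n_encounters,
            " encounters, ", st$n_positive_observations, " positive observations")
    write_vocabulary(fc$vocabulary, art$vocabulary)
    write_histories(histories, art$histories)
  }
  vocabulary <- read_vocabulary(art$vocabulary)
  histories <- read_histories(art$histories)

  ## fit
  if (!(resume && file.exists(art$model))) {
    message("[fit] Monte Carlo EM, K=", config$K, " W=", config$W,
            " N=", length(vocabulary))
    ctrl <- config$fit
    ctrl$seed <- seeds[["fit"]]
    fit <- fit_progression(histories, config$K, config$W, vocabulary,
                           anchors = anchors, control = ctrl)
    write_model(fit$model, art$model)
  }
  model <- read_model(art$model)

  ## simulate
  if (!(resume && file.exists(art$cohort))) {
    message("[simulate] generating ", config$n_patients, " patients")
    cohort <- generate_cohort(model, config$n_patients,
                              seed = seeds[["simulate"]],
                              horizon_years = config$horizon_years)
    write_cohort(cohort, art$cohort)
  }
  cohort <- read_cohort(art$cohort)

  ## report
  message("[report] writing cohort summaries")
  ss <- stage_summary(cohort)
  utils::write.csv(cbind(as.data.frame(ss), attr(ss, "prevalence")),
                   art$stage_summary, row.names = FALSE)
  write_retro_csv(single_complication_table(cohort), art$retro_single)
  if (!is.null(config$patterns)) {
    art$retro_patterns <- write_retro_csv(
      pattern_table(cohort, config$patterns), path("retro_patterns.csv"))
  }

  manifest <- list(
    package = "prognet",
    version = as.character(utils::packageVersion("prognet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed, derived_seeds = as.list(seeds),
    config = config[c("K", "W", "min_count", "granularity_years",
                      "n_patients", "horizon_years")],
    input_md5 = as.list(tools::md5sum(config$events)),
    artifacts = art[names(art) != "manifest"])
  jsonlite::write_json(manifest, art$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(art)
}
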