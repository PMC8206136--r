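# Orchestration: run configuration, the end-to-end pipeline stages, and a
# machine-readable run manifest. A thin command-line wrapper over these
# functions lives at inst/cli/luxdose.R.

run_config_keys <- c(
  "seed", "interval_s", "log_base", "log_offset", "anova_type",
  "threshold_lux", "interp", "design", "irradiance", "behavior"
)

#' Default run configuration
#'
#' Every stochastic stage derives its seed from the single `seed` entry;
#' the generator parameter blocks mirror [study_design()],
#' [irradiance_params()] and [behavior_params()] defaults.
#'
#' @param seed Master seed.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(
    list(
      seed = as.integer(seed),
      interval_s = 600,
      log_base = 10,
      log_offset = 1,
      anova_type = "II",
      threshold_lux = 3000,
      interp = "log",
      design = list(n_leaf_top = 41, n_under_leaf = 40, n_predator = 37,
                    n_paired_under_leaf = 26),
      irradiance = list(),
      behavior = list()
    ),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' @param config A configuration list.
#' @return The validated config (invisibly classed `run_config`); unknown
#'   keys raise an error naming them.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- default_run_config()
  merged <- utils::modifyList(unclass(defaults), config)
  stopifnot(merged$interval_s > 0, merged$log_base > 1,
            merged$threshold_lux > 0)
  merged$anova_type <- match.arg(merged$anova_type, c("II", "III"))
  merged$interp <- match.arg(merged$interp, c("log", "linear"))
  structure(merged, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip unchanged through serialisation.
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @describeIn read_run_config Write a config to YAML.
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(validate_run_config(config)), path)
  invisible(path)
}

config_objects <- function(config) {
  config <- validate_run_config(config)
  list(
    config = config,
    design = do.call(study_design,
                     c(config$design, list(interval_s = config$interval_s,
                                           seed = config$seed))),
    irr = do.call(irradiance_params, config$irradiance),
    behav = do.call(behavior_params, config$behavior)
  )
}

#' Process a simulated (or loaded) study into the tidy analysis table
#'
#' The measurement-recovery stage: characterises the four reference sensors
#' over the full grid, builds the global model, calibrates every deployed
#' sensor, converts its raw records to lux, and assembles the tidy
#' (individual, category, time_bin, lux) table through trimming, binning and
#' under-leaf pair averaging.
#'
#' @param study A [gen_field_study()] result with records (`sensors = TRUE`).
#' @param interp Light-axis interpolation space for the global model.
#' @return List: `model`, `calibrations`, `series` (per-sensor recovered lux
#'   at each interval end), `tidy` (the analysis table).
#' @export
process_study <- function(study, interp = "log") {
  if (is.null(study$records)) {
    stop("study carries no raw records; rerun gen_field_study(sensors = TRUE)",
         call. = FALSE)
  }
  grid <- characterize(study$reference_sensors,
                       interval_s = study$design$interval_s)
  model <- build_global_model(grid, interp = interp)
  sensors <- study$sensors
  cals <- purrr::map_dfr(seq_len(nrow(sensors)), function(i) {
    calibrate_sensor(sensors[i, ], model,
                     interval_s = study$design$interval_s)
  })
  series <- purrr::map_dfr(seq_len(nrow(sensors)), function(i) {
    rec <- study$records[study$records$sensor_id == sensors$sensor_id[i], ]
    out <- codes_to_lux(rec, cals[i, ], model)
    out[, c("sensor_id", "time_s", "lux")]
  })
  tidy <- build_tidy_table(series, study$deployments)
  list(model = model, calibrations = cals, series = series, tidy = tidy)
}

#' Run the inference stage on a tidy analysis table
#'
#' Normality screen on the raw lux values, log transform, AR(1) mixed-model
#' fit, Wald ANOVA, Tukey contrasts, descriptive summaries and threshold
#' exceedance.
#'
#' @param tidy A [build_tidy_table()] result.
#' @param config A `run_config`.
#' @return List: `screen`, `fit`, `anova`, `contrasts`, `summary`,
#'   `exceedance`.
#' @export
analyze_tidy <- function(tidy, config = default_run_config()) {
  config <- validate_run_config(config)
  fit <- fit_lmm_ar1(tidy, log_base = config$log_base,
                     offset = config$log_offset,
                     seed = child_seed(config$seed, 41))
  list(
    screen = normality_screen(tidy$lux, seed = child_seed(config$seed, 40)),
    fit = fit,
    anova = wald_anova(fit, type = config$anova_type),
    contrasts = tukey_contrasts(fit),
    summary = summarize_light(tidy),
    exceedance = exceedance(tidy, config$threshold_lux)
  )
}

write_stage_file <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full pipeline and write declared outputs plus a manifest
#'
#' Stages: `simulate-field` (synthetic study: truth, deployments, raw
#' records), `process` (calibration + tidy table), `analyze` (model tables),
#' `report` (summary tables and figures). Every file written is declared in
#' `manifest.json` with its MD5 hash; identical configurations produce
#' identical output hashes.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A `run_config` (list form accepted).
#' @param stages Character subset of the stages, in order.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, config = default_run_config(),
                         stages = c("simulate-field", "process", "analyze",
                                    "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  objs <- config_objects(config)
  config <- objs$config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  declare <- function(path) files <<- c(files, path)

  study <- gen_field_study(objs$design, objs$irr, objs$behav)
  if ("simulate-field" %in% stages) {
    declare(write_stage_file(study$truth, file.path(out_dir, "truth_lux.csv")))
    dep_flat <- dplyr::mutate(
      study$deployments,
      sensor_ids = vapply(.data$sensor_ids, paste, "", collapse = ";"),
      dplyr::across(dplyr::where(hms::is_hms), as.character)
    )
    declare(write_stage_file(dep_flat, file.path(out_dir, "deployments.csv")))
    declare(write_stage_file(study$records, file.path(out_dir, "raw_records.csv")))
    declare(write_stage_file(study$sensors, file.path(out_dir, "sensor_params.csv")))
  }
  processed <- NULL
  if (any(c("process", "analyze", "report") %in% stages)) {
    processed <- process_study(study, interp = config$interp)
  }
  if ("process" %in% stages) {
    declare(write_stage_file(processed$series,
                             file.path(out_dir, "recovered_lux.csv")))
    tidy_flat <- dplyr::mutate(processed$tidy,
                               time_bin = as.character(.data$time_bin))
    declare(write_stage_file(tidy_flat, file.path(out_dir, "tidy_light.csv")))
  }
  results <- NULL
  if (any(c("analyze", "report") %in% stages)) {
    results <- analyze_tidy(processed$tidy, config)
  }
  if ("analyze" %in% stages) {
    declare(write_stage_file(results$anova, file.path(out_dir, "anova.csv")))
    declare(write_stage_file(results$contrasts,
                             file.path(out_dir, "contrasts.csv")))
    declare(write_stage_file(results$screen,
                             file.path(out_dir, "normality_screen.csv")))
  }
  if ("report" %in% stages) {
    summ_flat <- dplyr::mutate(results$summary,
                               time_bin = as.character(.data$time_bin))
    declare(write_stage_file(summ_flat, file.path(out_dir, "summary.csv")))
    declare(write_stage_file(results$exceedance$by_category,
                             file.path(out_dir, "exceedance.csv")))
    fig <- file.path(out_dir, "daily_profiles.png")
    ggplot2::ggsave(fig, plot_daily_profiles(results$summary),
                    width = 7, height = 4.5, dpi = 150)
    declare(fig)
    fig2 <- file.path(out_dir, "daily_boxes.png")
    ggplot2::ggsave(fig2, plot_daily_boxes(results$summary),
                    width = 7, height = 4.5, dpi = 150)
    declare(fig2)
  }
  manifest <- list(
    package = "luxdose",
    version = as.character(utils::packageVersion("luxdose")),
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
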