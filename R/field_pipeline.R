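# Field-data pipeline: per-sensor lux series + deployment metadata -> the
# tidy (individual, category, time_bin, lux) analysis table and descriptive
# summaries.
#
# The analysis window is 09:30-16:00 local time at 10-min resolution: a
# reading stamped at clock tick t integrates the preceding 10 minutes
# (t - 10 min, t], and the tick grid 09:30, 09:40, ..., 16:00 has exactly 40
# ticks. Tahiti observes no daylight saving, so clock time is plain civil
# time.

FIELD_CATEGORIES <- c("leaf_top", "under_leaf", "predator")

#' The 40-tick analysis bin grid
#'
#' Clock ticks 09:30, 09:40, ..., 16:00 (inclusive): 40 ten-minute bins, each
#' labelled by the interval end.
#'
#' @param start,end Window bounds as "HH:MM" strings or seconds.
#' @param interval_s Bin width in seconds.
#' @return An `hms` vector of tick labels.
#' @export
bin_grid <- function(start = "09:30", end = "16:00", interval_s = 600) {
  secs_to_hms(seq(clock_s(start), clock_s(end), by = interval_s))
}

#' Deployment metadata constructor
#'
#' One row per deployed individual: who, which category and site, which
#' sensor(s), and the recording vs meaningful-measurement clock windows.
#' Under-leaf individuals may carry two bracketing sensors; other categories
#' exactly one.
#'
#' @param subject_id Individual identifier.
#' @param category One of `"leaf_top"`, `"under_leaf"`, `"predator"`.
#' @param site Site label.
#' @param date Recording date (`Date` or string).
#' @param sensor_ids Character vector of one or two sensor ids.
#' @param recording_start,recording_end Sensor on/off clock times.
#' @param measurement_start,measurement_end Meaningful-measurement window
#'   (nested in the recording window).
#' @return A one-row deployment tibble.
#' @export
deployment <- function(subject_id, category, site, date, sensor_ids,
                       recording_start = "08:30", recording_end = "16:30",
                       measurement_start = "09:30",
                       measurement_end = "16:00") {
  category <- match.arg(category, FIELD_CATEGORIES)
  sensor_ids <- as.character(sensor_ids)
  if (category == "under_leaf") {
    if (!length(sensor_ids) %in% 1:2) {
      stop("under_leaf deployments carry one or two sensors", call. = FALSE)
    }
  } else if (length(sensor_ids) != 1) {
    stop(category, " deployments carry exactly one sensor", call. = FALSE)
  }
  rs <- clock_s(recording_start); re <- clock_s(recording_end)
  ms <- clock_s(measurement_start); me <- clock_s(measurement_end)
  if (!(rs <= ms && ms < me && me <= re)) {
    stop("measurement window must be nested in the recording window",
         call. = FALSE)
  }
  tibble::tibble(
    subject_id = as.character(subject_id), category = category,
    site = as.character(site), date = as.Date(date),
    sensor_ids = list(sensor_ids),
    recording_start = secs_to_hms(rs), measurement_start = secs_to_hms(ms),
    measurement_end = secs_to_hms(me), recording_end = secs_to_hms(re)
  )
}

#' Bin a fine-resolution lux series into interval means
#'
#' Aggregates a series sampled finer than the duty cycle into one mean value
#' per interval `(t - interval_s, t]`, stamped at the interval end — the
#' same convention the sensor's integrating counter uses. Useful for turning
#' ground-truth series into bin-level references.
#'
#' @param series Tibble with `time_s` and `lux` (optionally `sensor_id`,
#'   preserved by grouping).
#' @param interval_s Bin width in seconds.
#' @return Tibble with one row per (sensor, interval end).
#' @export
bin_series <- function(series, interval_s = 600) {
  grouped <- if ("sensor_id" %in% names(series)) {
    dplyr::group_by(series, .data$sensor_id)
  } else {
    series
  }
  grouped |>
    dplyr::mutate(time_s = ceiling(.data$time_s / interval_s) * interval_s) |>
    dplyr::group_by(.data$time_s, .add = TRUE) |>
    dplyr::summarise(lux = mean(.data$lux), .groups = "drop")
}

#' Trim a lux series to the meaningful-measurement window and bin it
#'
#' Keeps only readings whose clock tick falls on the analysis grid and inside
#' the deployment's measurement window, and re-labels timestamps as bin
#' ticks. Readings dropped for either reason are counted in the
#' `"excluded"` attribute so binning conserves records.
#'
#' @param series Tibble with `time_s` (seconds since midnight at the interval
#'   end) and `lux`.
#' @param deployment A [deployment()] row.
#' @param grid Analysis tick grid from [bin_grid()].
#' @return Tibble (`time_bin`, `lux`); attribute `excluded` holds the counts
#'   of readings dropped as off-grid or outside the window.
#' @export
align_and_trim <- function(series, deployment, grid = bin_grid()) {
  ticks <- round(as.numeric(grid))
  t <- round(series$time_s)
  on_grid <- t %in% ticks
  in_window <- t >= as.numeric(deployment$measurement_start) &
    t <= as.numeric(deployment$measurement_end)
  keep <- on_grid & in_window
  out <- tibble::tibble(
    time_bin = secs_to_hms(t[keep]),
    lux = series$lux[keep]
  )
  if (nrow(out) == 0) {
    message("align_and_trim: no overlap between series and measurement ",
            "window for ", deployment$subject_id)
  }
  attr(out, "excluded") <- c(
    off_grid = sum(!on_grid),
    outside_window = sum(on_grid & !in_window)
  )
  out
}

#' Average the two under-leaf sensor series of one individual
#'
#' Binwise arithmetic mean of two series on the common grid; bins present in
#' only one series take that series' value and are flagged `single_source`.
#'
#' @param a,b Binned series tibbles (`time_bin`, `lux`).
#' @param category Deployment category; paired sensors only occur under
#'   leaves, so anything else is an error.
#' @return Tibble (`time_bin`, `lux`, `single_source`).
#' @export
pair_average <- function(a, b, category = "under_leaf") {
  if (!identical(category, "under_leaf")) {
    stop("paired sensors are only used for under_leaf deployments",
         call. = FALSE)
  }
  dplyr::full_join(
    dplyr::rename(a, lux_a = "lux"), dplyr::rename(b, lux_b = "lux"),
    by = "time_bin"
  ) |>
    dplyr::arrange(.data$time_bin) |>
    dplyr::mutate(
      single_source = is.na(.data$lux_a) | is.na(.data$lux_b),
      lux = dplyr::if_else(
        .data$single_source,
        dplyr::coalesce(.data$lux_a, .data$lux_b),
        (.data$lux_a + .data$lux_b) / 2
      )
    ) |>
    dplyr::select("time_bin", "lux", "single_source")
}

#' Assemble the tidy analysis table
#'
#' Joins binned per-sensor series to deployment metadata, averages paired
#' under-leaf sensors, and emits the long-format analysis table with at most
#' one row per (individual, time_bin). Missing bins stay absent — they are
#' excluded from analysis, not zero-filled.
#'
#' @param series_tbl Tibble (`sensor_id`, `time_s`, `lux`) of lux series for
#'   all sensors (pre-binning; trimming happens here per deployment).
#' @param deployments Tibble of [deployment()] rows.
#' @param grid Analysis tick grid.
#' @return A tibble (`individual`, `category`, `time_bin`, `time_idx`,
#'   `lux`), `time_idx` being the 0-based bin index used as the model's time
#'   covariate.
#' @export
build_tidy_table <- function(series_tbl, deployments, grid = bin_grid()) {
  out <- purrr::map_dfr(seq_len(nrow(deployments)), function(i) {
    dep <- deployments[i, ]
    ids <- dep$sensor_ids[[1]]
    binned <- purrr::map(ids, function(sid) {
      s <- series_tbl[series_tbl$sensor_id == sid, c("time_s", "lux")]
      align_and_trim(s, dep, grid = grid)
    })
    series <- if (length(binned) == 2) {
      pair_average(binned[[1]], binned[[2]])
    } else {
      binned[[1]]
    }
    if (nrow(series) == 0) return(NULL)
    tibble::tibble(
      individual = dep$subject_id, category = dep$category,
      time_bin = series$time_bin, lux = series$lux
    )
  })
  if (anyDuplicated(out[, c("individual", "time_bin")])) {
    stop("duplicate (individual, time_bin) rows; check deployment metadata",
         call. = FALSE)
  }
  out |>
    dplyr::mutate(
      category = factor(.data$category, levels = FIELD_CATEGORIES),
      time_idx = match(round(as.numeric(.data$time_bin)),
                       round(as.numeric(grid))) - 1L
    ) |>
    dplyr::select("individual", "category", "time_bin", "time_idx", "lux")
}

#' Per-category, per-bin descriptive summary
#'
#' For every (category, time_bin): the mean and its standard error, the
#' boxplot five-number summary (median, Q1, Q3) and the 1.5 x IQR whisker
#' bounds, and the number of individuals. The SE of a single reading is
#' undefined and reported as `NA`.
#'
#' @param tidy A [build_tidy_table()] result.
#' @return A tibble with one row per (category, time_bin).
#' @export
summarize_light <- function(tidy) {
  if (nrow(tidy) == 0) stop("empty analysis table", call. = FALSE)
  tidy |>
    dplyr::group_by(.data$category, .data$time_bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$lux),
      se = ifelse(.data$n > 1, stats::sd(.data$lux) / sqrt(.data$n), NA_real_),
      median = stats::median(.data$lux),
      q1 = unname(stats::quantile(.data$lux, 0.25)),
      q3 = unname(stats::quantile(.data$lux, 0.75)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      iqr = .data$q3 - .data$q1,
      whisker_lo = .data$q1 - 1.5 * .data$iqr,
      whisker_hi = .data$q3 + 1.5 * .data$iqr
    )
}

#' Fold difference between two category means at one bin
#'
#' @param summary A [summarize_light()] table.
#' @param bin Bin label (`hms` or "HH:MM" string).
#' @param cat_a,cat_b Numerator and denominator categories.
#' @return The ratio `mean(cat_a) / mean(cat_b)` (`NA` with a warning if the
#'   denominator mean is zero).
#' @export
fold_difference <- function(summary, bin, cat_a, cat_b) {
  b <- secs_to_hms(clock_s(bin))
  row_a <- summary[summary$category == cat_a & summary$time_bin == b, ]
  row_b <- summary[summary$category == cat_b & summary$time_bin == b, ]
  if (nrow(row_a) != 1 || nrow(row_b) != 1) {
    stop("no summary row for the requested category/bin", call. = FALSE)
  }
  if (row_b$mean == 0) {
    warning("zero denominator mean; fold difference undefined")
    return(NA_real_)
  }
  row_a$mean / row_b$mean
}

#' Threshold exceedance by category
#'
#' Fraction of readings above an illuminance threshold per category, plus
#' each individual's maximum reading (used, e.g., to ask how rarely foraging
#' predators expose themselves to more than 3000 lux).
#'
#' @param tidy A [build_tidy_table()] result.
#' @param threshold_lux Positive threshold.
#' @return List with `by_category` (category, n, frac_above) and
#'   `individual_max` (individual, category, max_lux).
#' @export
exceedance <- function(tidy, threshold_lux = 3000) {
  stopifnot(threshold_lux > 0)
  list(
    by_category = tidy |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(
        n = dplyr::n(),
        frac_above = mean(.data$lux > threshold_lux),
        .groups = "drop"
      ),
    individual_max = tidy |>
      dplyr::group_by(.data$individual, .data$category) |>
      dplyr::summarise(max_lux = max(.data$lux), .groups = "drop")
  )
}
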