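# Characterisation and calibration: from raw counter codes to lux.
#
# Four reference sensors are measured over a 6 x 4 x 4 factorial grid of
# light, temperature and battery voltage (96 cells each); averaging their
# light codes gives a global piecewise-linear code->lux model. Every deployed
# sensor then gets a three-point temperature calibration and one-point light
# and battery-voltage calibrations, after which its raw records can be
# inverted to illuminance.

#' Characterisation grid axes
#'
#' The bench grid: six light levels, four temperatures and four battery
#' voltages — a full factorial of 96 cells per sensor.
#'
#' @param light_klux,temp_C,vbat_V Ordered axis values.
#' @return A named list of the three axes.
#' @export
calibration_axes <- function(light_klux = c(0.5, 1, 5, 10, 50, 100),
                             temp_C = c(25, 35, 45, 55),
                             vbat_V = c(3.9, 4.0, 4.1, 4.2)) {
  stopifnot(
    !is.unsorted(light_klux, strictly = TRUE),
    !is.unsorted(temp_C, strictly = TRUE),
    !is.unsorted(vbat_V, strictly = TRUE)
  )
  list(light_klux = light_klux, temp_C = temp_C, vbat_V = vbat_V)
}

#' Measure sensors over the characterisation grid
#'
#' Runs each sensor through one duty-cycle interval at every grid cell's
#' constant conditions and records the steady-state codes. Noise is off by
#' default so characterisation is deterministic; set `noise = TRUE` to keep
#' each sensor's own per-interval noise.
#'
#' @param sensors Tibble of [sensor_params()] rows (one or more sensors).
#' @param axes Grid axes from [calibration_axes()].
#' @param interval_s Integration interval in seconds.
#' @param noise Keep per-interval dose noise? Default `FALSE`.
#' @param seed Seed used when `noise = TRUE`.
#' @return Tibble with one row per (sensor, cell): `sensor_id`, `light_klux`,
#'   `temp_C`, `vbat_V`, `light_code`, `temp_code`, `vbat_code`.
#' @export
characterize <- function(sensors, axes = calibration_axes(),
                         interval_s = 600, noise = FALSE, seed = 1L) {
  stopifnot(nrow(sensors) >= 1)
  if (!all(c("light_klux", "temp_C", "vbat_V") %in% names(axes)) ||
      any(lengths(axes[c("light_klux", "temp_C", "vbat_V")]) == 0)) {
    stop("`axes` must provide non-empty light_klux, temp_C and vbat_V",
         call. = FALSE)
  }
  cells <- tidyr::crossing(
    light_klux = axes$light_klux,
    temp_C = axes$temp_C,
    vbat_V = axes$vbat_V
  )
  purrr::map_dfr(seq_len(nrow(sensors)), function(i) {
    p <- sensors[i, ]
    if (!noise) p$noise_cv <- 0
    purrr::map_dfr(seq_len(nrow(cells)), function(j) {
      cell <- cells[j, ]
      env <- constant_env(1000 * cell$light_klux, cell$temp_C, cell$vbat_V,
                          duration_s = interval_s, step_s = interval_s / 2)
      rec <- simulate_counts(env, p, interval_s = interval_s,
                             seed = child_seed(seed, (i - 1) * nrow(cells) + j))
      tibble::tibble(
        sensor_id = p$sensor_id,
        light_klux = cell$light_klux, temp_C = cell$temp_C,
        vbat_V = cell$vbat_V,
        light_code = rec$light_code,
        temp_code = rec$temp_code, vbat_code = rec$vbat_code
      )
    })
  })
}

#' Build the global code-to-lux model from reference characterisations
#'
#' Averages the light-sensor codes cellwise across the reference sensors and
#' retains the grid axes for piecewise-linear interpolation. The reference
#' temperature and battery-voltage encodings (mean codes per axis value) are
#' kept so deployed sensors' codes can be decoded to physical units.
#'
#' @param grid Characterisation tibble from [characterize()] for the
#'   reference sensors (four, by default study design).
#' @param interp Light-axis interpolation space: `"log"` (piecewise linear in
#'   log10 lux, the default; the grid spans 2.3 decades) or `"linear"`.
#' @return A `global_model` object.
#' @export
build_global_model <- function(grid, interp = c("log", "linear")) {
  interp <- match.arg(interp)
  axes <- calibration_axes(
    light_klux = sort(unique(grid$light_klux)),
    temp_C = sort(unique(grid$temp_C)),
    vbat_V = sort(unique(grid$vbat_V))
  )
  n_cells <- prod(lengths(axes))
  per_sensor <- dplyr::count(grid, .data$sensor_id)
  if (any(per_sensor$n != n_cells)) {
    stop("each sensor must cover the full factorial grid (",
         n_cells, " cells)", call. = FALSE)
  }
  cellwise <- grid |>
    dplyr::group_by(.data$light_klux, .data$temp_C, .data$vbat_V) |>
    dplyr::summarise(code = mean(.data$light_code), .groups = "drop") |>
    dplyr::arrange(.data$vbat_V, .data$temp_C, .data$light_klux)
  codes <- array(
    cellwise$code,
    dim = lengths(axes),
    dimnames = lapply(axes, as.character)
  )
  if (any(apply(codes, c(2, 3), is.unsorted))) {
    stop("reference codes must increase with light level at fixed temp/vbat",
         call. = FALSE)
  }
  temp_ref <- grid |>
    dplyr::group_by(temp_C = .data$temp_C) |>
    dplyr::summarise(code = mean(.data$temp_code), .groups = "drop")
  vbat_ref <- grid |>
    dplyr::group_by(vbat_V = .data$vbat_V) |>
    dplyr::summarise(code = mean(.data$vbat_code), .groups = "drop")
  structure(
    list(axes = axes, codes = codes, temp_ref = temp_ref,
         vbat_ref = vbat_ref, interp = interp,
         n_sensors = nrow(per_sensor)),
    class = "global_model"
  )
}

#' @export
print.global_model <- function(x, ...) {
  cat("<global_model> piecewise-linear code->lux map\n")
  cat("  grid:", paste(lengths(x$axes), collapse = " x "),
      sprintf("(%d cells), averaged over %d reference sensor(s)\n",
              prod(lengths(x$axes)), x$n_sensors))
  cat("  light interpolation space:", x$interp, "\n")
  invisible(x)
}

# Linear interpolation with linear extrapolation from the end segments.
interp_extrap <- function(x, y, xout) {
  stopifnot(length(x) >= 2)
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  n <- length(x)
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

# Reference light codes at the six grid light levels, bilinearly interpolated
# over (temp_C, vbat_V) with linear extrapolation at the edges. Vectorised
# over records: returns an n x n_light matrix.
bilinear_codes <- function(model, temp_C, vbat_V) {
  vb <- model$axes$vbat_V
  n <- length(temp_C)
  j <- pmin(pmax(findInterval(vbat_V, vb), 1), length(vb) - 1)
  w <- (vbat_V - vb[j]) / (vb[j + 1] - vb[j])
  vapply(seq_along(model$axes$light_klux), function(l) {
    slab <- model$codes[l, , ]
    by_vbat <- vapply(seq_along(vb), function(k) {
      interp_extrap(model$axes$temp_C, slab[, k], temp_C)
    }, numeric(n))
    if (is.null(dim(by_vbat))) by_vbat <- matrix(by_vbat, nrow = n)
    by_vbat[cbind(seq_len(n), j)] * (1 - w) +
      by_vbat[cbind(seq_len(n), j + 1)] * w
  }, numeric(n))
}

model_codes_at <- function(model, temp_C, vbat_V) {
  drop(bilinear_codes(model, temp_C, vbat_V))
}

#' Calibrate one sensor against the global model
#'
#' Bench measurement at the calibration conditions (temperature 25, 45 and
#' 55 degC; light 5 klux; battery 4.1 V) gives a three-point piecewise-linear
#' temperature map, a one-point multiplicative light-gain correction
#' (reference code over sensor code at the 5 klux / 25 degC / 4.1 V anchor)
#' and a one-point additive battery-voltage code correction.
#'
#' @param sensor A single [sensor_params()] row.
#' @param model The [build_global_model()] result.
#' @param cal_temps_C Temperature anchors (three values).
#' @param cal_light_klux,cal_vbat_V Light and voltage anchor conditions.
#' @param interval_s Integration interval.
#' @param noise Keep measurement noise during the bench readings?
#' @param seed Seed used when `noise = TRUE`.
#' @return One-row tibble of class `sensor_calibration`: temperature-anchor
#'   codes, `light_gain` and `vbat_offset`.
#' @export
calibrate_sensor <- function(sensor, model,
                             cal_temps_C = c(25, 45, 55),
                             cal_light_klux = 5, cal_vbat_V = 4.1,
                             interval_s = 600, noise = FALSE, seed = 1L) {
  stopifnot(nrow(sensor) == 1)
  if (length(cal_temps_C) < 3) {
    stop("three-point temperature calibration needs 3 anchor temperatures",
         call. = FALSE)
  }
  meas <- characterize(
    sensor,
    axes = list(light_klux = cal_light_klux, temp_C = sort(cal_temps_C),
                vbat_V = cal_vbat_V),
    interval_s = interval_s, noise = noise, seed = seed
  )
  anchor <- meas[meas$temp_C == min(cal_temps_C), ]
  ref_code <- model_codes_at(model, min(cal_temps_C), cal_vbat_V)[
    match(cal_light_klux, model$axes$light_klux)]
  if (is.na(ref_code)) {
    stop("calibration light level must be a grid node of the global model",
         call. = FALSE)
  }
  ref_vbat_code <- interp_extrap(model$vbat_ref$vbat_V, model$vbat_ref$code,
                                 cal_vbat_V)
  out <- tibble::tibble(
    sensor_id = sensor$sensor_id,
    temp_C_anchors = list(sort(cal_temps_C)),
    temp_code_anchors = list(meas$temp_code[order(meas$temp_C)]),
    light_gain = ref_code / anchor$light_code,
    vbat_offset = ref_vbat_code - anchor$vbat_code
  )
  if (!is.finite(out$light_gain) || out$light_gain <= 0) {
    stop("degenerate light calibration (non-positive anchor code)",
         call. = FALSE)
  }
  class(out) <- c("sensor_calibration", class(out))
  out
}

#' Identity calibration (uncalibrated decoding)
#'
#' A pass-through calibration that applies no per-sensor correction: unit
#' light gain, zero voltage offset, and temperature anchors taken from the
#' reference encoding. Used to quantify what per-sensor calibration buys.
#'
#' @param model A `global_model`.
#' @param sensor_id Identifier to stamp on the calibration row.
#' @return A `sensor_calibration` row.
#' @export
identity_calibration <- function(model, sensor_id = "uncalibrated") {
  anchors <- c(25, 45, 55)
  codes <- interp_extrap(model$temp_ref$temp_C, model$temp_ref$code, anchors)
  out <- tibble::tibble(
    sensor_id = sensor_id,
    temp_C_anchors = list(anchors),
    temp_code_anchors = list(codes),
    light_gain = 1,
    vbat_offset = 0
  )
  class(out) <- c("sensor_calibration", class(out))
  out
}

decode_temp <- function(temp_code, cal) {
  interp_extrap(cal$temp_code_anchors[[1]], cal$temp_C_anchors[[1]], temp_code)
}

decode_vbat <- function(vbat_code, cal, model) {
  interp_extrap(model$vbat_ref$code, model$vbat_ref$vbat_V,
                vbat_code + cal$vbat_offset)
}

# Invert the six-node light axis at one decoded (temp, vbat): monotone
# piecewise-linear interpolation of code -> lux in the model's interpolation
# space; below the bottom node a linear segment through the extrapolated
# dark-code origin; above the top node linear extrapolation of the top
# segment.
invert_light_code <- function(scaled_code, codes6, model) {
  lux6 <- 1000 * model$axes$light_klux
  n <- length(lux6)
  out <- numeric(length(scaled_code))
  yaxis <- if (model$interp == "log") log10(lux6) else lux6
  dark_code <- max(0, codes6[1] - lux6[1] * (codes6[2] - codes6[1]) /
                     (lux6[2] - lux6[1]))
  below <- scaled_code < codes6[1]
  above <- scaled_code > codes6[n]
  mid <- !below & !above
  if (any(mid)) {
    v <- stats::approx(codes6, yaxis, xout = scaled_code[mid])$y
    out[mid] <- if (model$interp == "log") 10^v else v
  }
  if (any(above)) {
    s <- (yaxis[n] - yaxis[n - 1]) / (codes6[n] - codes6[n - 1])
    v <- yaxis[n] + s * (scaled_code[above] - codes6[n])
    out[above] <- if (model$interp == "log") 10^v else v
  }
  if (any(below)) {
    out[below] <- pmax(0, lux6[1] * (scaled_code[below] - dark_code) /
                         (codes6[1] - dark_code))
  }
  out
}

#' Convert raw records to illuminance
#'
#' Decodes each record's temperature and battery codes through the sensor's
#' calibration, applies the one-point light-gain correction to the light
#' code, and inverts the global piecewise-linear model at the decoded
#' conditions. Records whose decoded temperature or voltage falls outside a
#' broad plausibility range are flagged (`suspect = TRUE`) but retained.
#'
#' @param records Raw record tibble (`light_code`, `temp_code`, `vbat_code`).
#' @param cal The sensor's [calibrate_sensor()] row.
#' @param model The [build_global_model()] result.
#' @param temp_range_C,vbat_range_V Plausibility ranges for flagging.
#' @return `records` with added `temp_C`, `vbat_V`, `lux`, `suspect` columns.
#' @export
codes_to_lux <- function(records, cal, model,
                         temp_range_C = c(0, 70),
                         vbat_range_V = c(3.5, 4.6)) {
  if (nrow(records) == 0) stop("`records` is empty", call. = FALSE)
  temp_C <- decode_temp(records$temp_code, cal)
  vbat_V <- decode_vbat(records$vbat_code, cal, model)
  scaled <- records$light_code * cal$light_gain
  codes_mat <- bilinear_codes(model, temp_C, vbat_V)
  if (is.null(dim(codes_mat))) codes_mat <- matrix(codes_mat, nrow = 1)
  lux <- vapply(seq_len(nrow(records)), function(i) {
    invert_light_code(scaled[i], codes_mat[i, ], model)
  }, numeric(1))
  dplyr::mutate(
    records,
    temp_C = temp_C, vbat_V = vbat_V, lux = lux,
    suspect = temp_C < temp_range_C[1] | temp_C > temp_range_C[2] |
      vbat_V < vbat_range_V[1] | vbat_V > vbat_range_V[2]
  )
}

#' Batch validation: calibrated-reading stability across sensors
#'
#' Re-measures a batch of sensors at bench validation conditions (by default
#' the nine used for the deployed batch: 0.5, 5 and 50 klux crossed with 25,
#' 30 and 35 degC at 4.1 V), converts each reading to lux, and summarises
#' per-condition stability as the coefficient of variation sigma/mean across
#' sensors, plus the mean nonlinearity ratio reported/actual - 1.
#'
#' @param sensors Tibble of sensor parameter rows (>= 2 sensors).
#' @param model Global model the batch is calibrated against.
#' @param cals Optional pre-computed calibrations (one row per sensor, same
#'   order); computed noiselessly if omitted.
#' @param light_klux,temp_C,vbat_V Validation conditions (crossed).
#' @param interval_s Integration interval.
#' @param noise Keep per-interval measurement noise (default `TRUE`, as on
#'   the bench each reading is a single noisy interval).
#' @param seed Seed for the measurement noise.
#' @param calibrated Apply per-sensor calibration? `FALSE` decodes every
#'   sensor through [identity_calibration()] instead.
#' @return Tibble with one row per condition: `light_klux`, `temp_C`, `n`,
#'   `mean_lux`, `sd_lux`, `cv` (sigma/mean), `nonlin` (mean reported/actual
#'   - 1). The worst-case condition is available via [worst_cv()].
#' @export
validate_batch <- function(sensors, model, cals = NULL,
                           light_klux = c(0.5, 5, 50),
                           temp_C = c(25, 30, 35), vbat_V = 4.1,
                           interval_s = 600, noise = TRUE, seed = 1L,
                           calibrated = TRUE) {
  stopifnot(nrow(sensors) >= 2)
  if (calibrated && is.null(cals)) {
    cals <- purrr::map_dfr(seq_len(nrow(sensors)), function(i) {
      calibrate_sensor(sensors[i, ], model, interval_s = interval_s)
    })
  }
  axes <- list(light_klux = light_klux, temp_C = temp_C, vbat_V = vbat_V)
  meas <- characterize(sensors, axes = axes, interval_s = interval_s,
                       noise = noise, seed = seed)
  readings <- purrr::map_dfr(seq_len(nrow(sensors)), function(i) {
    cal <- if (calibrated) cals[i, ] else identity_calibration(model)
    rec <- meas[meas$sensor_id == sensors$sensor_id[i], ]
    out <- codes_to_lux(rec, cal, model)
    out[, c("sensor_id", "light_klux", "temp_C", "vbat_V", "lux")]
  })
  readings |>
    dplyr::group_by(.data$light_klux, .data$temp_C) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_lux = mean(.data$lux),
      sd_lux = stats::sd(.data$lux),
      cv = .data$sd_lux / .data$mean_lux,
      nonlin = .data$mean_lux / (1000 * .data$light_klux[1]) - 1,
      .groups = "drop"
    )
}

#' @describeIn validate_batch Worst-case sigma/mean across conditions.
#' @param validation A [validate_batch()] table.
#' @export
worst_cv <- function(validation) {
  max(validation$cv, na.rm = TRUE)
}
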