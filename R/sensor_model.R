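# Behavioural model of the duty-cycled harvester-based light logger.
#
# The harvester's ring-oscillator frequency tracks photovoltaic current, which
# is proportional to illuminance to first order; a low-power 24-bit counter
# accumulates oscillations over each sleep interval, so the counter value read
# (and reset) at each wake-up is a time-integrated light dose.

COUNTER_BITS <- 24L

#' Sensor parameter set
#'
#' Describes one simulated sensor: the affine lux -> oscillation-rate law,
#' its multiplicative temperature and battery-voltage dependence, per-interval
#' multiplicative read noise, and the affine encodings its on-board
#' temperature and battery-voltage channels use.
#'
#' @param sensor_id Character identifier.
#' @param gain Oscillations per second per lux at 25 degC and 4.1 V. Must be
#'   positive.
#' @param dark_rate Oscillations per second at 0 lux (leakage-driven floor).
#' @param temp_coeff Fractional rate change per degC away from 25 degC.
#' @param vbat_coeff Fractional rate change per volt away from 4.1 V.
#' @param noise_cv Coefficient of variation of the multiplicative dose noise
#'   drawn once per interval. Zero disables noise.
#' @param temp_sensor_offset,temp_sensor_gain Affine encoding of the raw
#'   temperature code: `temp_code = round(offset + gain * temp_C)`. The
#'   nominal channel has offset 0 and gain 10 (codes in tenths of a degree).
#' @param vbat_sensor_offset Additive distortion of the battery-voltage code:
#'   `vbat_code = round(1000 * vbat_V + offset)` (nominal offset 0, codes in
#'   millivolts).
#'
#' @return A one-row tibble of class `sensor_params`.
#' @export
#' @examples
#' sensor_params("s1", gain = 0.2)
sensor_params <- function(sensor_id,
                          gain = 0.2,
                          dark_rate = 8,
                          temp_coeff = -0.002,
                          vbat_coeff = 0.1,
                          noise_cv = 0.05,
                          temp_sensor_offset = 0,
                          temp_sensor_gain = 10,
                          vbat_sensor_offset = 0) {
  stopifnot(gain > 0, dark_rate >= 0, noise_cv >= 0, temp_sensor_gain > 0)
  out <- tibble::tibble(
    sensor_id = as.character(sensor_id),
    gain = gain, dark_rate = dark_rate,
    temp_coeff = temp_coeff, vbat_coeff = vbat_coeff,
    noise_cv = noise_cv, counter_bits = COUNTER_BITS,
    temp_sensor_offset = temp_sensor_offset,
    temp_sensor_gain = temp_sensor_gain,
    vbat_sensor_offset = vbat_sensor_offset
  )
  class(out) <- c("sensor_params", class(out))
  out
}

#' Draw a batch of sensors from the default fabrication-spread model
#'
#' Sensor-to-sensor variation is modelled as: gain lognormal around the
#' nominal 0.2 osc/s/lux (sdlog `gain_sdlog`), dark rate Gamma with mean
#' `dark_mean`, temperature and battery coefficients Gaussian around the
#' nominal values, and Gaussian distortions of the temperature and voltage
#' encodings. These spreads are modelling assumptions, documented in the
#' methods vignette; they motivate the per-sensor calibration stage.
#'
#' @param n Number of sensors.
#' @param seed Integer seed (mandatory; batches are reproducible).
#' @param gain_sdlog Log-sd of the gain spread.
#' @param dark_mean,dark_sd Mean and sd of the dark-rate Gamma.
#' @param temp_coeff_mean,temp_coeff_sd Gaussian spread of `temp_coeff`.
#' @param vbat_coeff_mean,vbat_coeff_sd Gaussian spread of `vbat_coeff`.
#' @param noise_cv Per-interval dose-noise CV shared by the batch.
#' @param id_prefix Prefix for generated sensor ids.
#' @return A tibble with one `sensor_params` row per sensor.
#' @export
draw_sensor_batch <- function(n, seed,
                              gain_sdlog = 0.25,
                              dark_mean = 8, dark_sd = 4,
                              temp_coeff_mean = -0.002, temp_coeff_sd = 0.004,
                              vbat_coeff_mean = 0.1, vbat_coeff_sd = 0.05,
                              noise_cv = 0.05,
                              id_prefix = "sensor") {
  stopifnot(n >= 1, !missing(seed))
  local_seed(seed)
  shape <- (dark_mean / dark_sd)^2
  purrr::map_dfr(seq_len(n), function(i) {
    sensor_params(
      sensor_id = sprintf("%s_%02d", id_prefix, i),
      gain = stats::rlnorm(1, log(0.2), gain_sdlog),
      dark_rate = stats::rgamma(1, shape = shape, scale = dark_mean / shape),
      temp_coeff = stats::rnorm(1, temp_coeff_mean, temp_coeff_sd),
      vbat_coeff = stats::rnorm(1, vbat_coeff_mean, vbat_coeff_sd),
      noise_cv = noise_cv,
      temp_sensor_offset = stats::rnorm(1, 0, 30),
      temp_sensor_gain = stats::rnorm(1, 10, 0.3),
      vbat_sensor_offset = stats::rnorm(1, 0, 25)
    )
  })
}

#' Reference sensor with nominal parameters and no noise
#'
#' @param sensor_id Identifier.
#' @return A one-row `sensor_params` tibble.
#' @export
reference_sensor <- function(sensor_id = "reference") {
  sensor_params(sensor_id, noise_cv = 0)
}

#' Instantaneous oscillation rate of the harvester readout
#'
#' The rate is affine in illuminance with multiplicative first-order
#' temperature and battery-voltage corrections, clamped at zero:
#' `rate = (dark_rate + gain * lux) * (1 + temp_coeff * (temp_C - 25)) *
#' (1 + vbat_coeff * (vbat_V - 4.1))`.
#'
#' @param lux Illuminance (lux), non-negative; vectorised.
#' @param temp_C Temperature in degC.
#' @param vbat_V Battery voltage in volts.
#' @param params A `sensor_params` row.
#' @return Oscillation rate in oscillations per second (>= 0).
#' @export
#' @examples
#' oscillation_rate(5000, 25, 4.1, sensor_params("s", gain = 0.2, dark_rate = 0))
oscillation_rate <- function(lux, temp_C, vbat_V, params) {
  if (any(lux < 0)) stop("`lux` must be non-negative", call. = FALSE)
  rate <- (params$dark_rate + params$gain * lux) *
    (1 + params$temp_coeff * (temp_C - 25)) *
    (1 + params$vbat_coeff * (vbat_V - 4.1))
  pmax(rate, 0)
}

#' 24-bit oscillation counter
#'
#' A mutable counter with the wrap-on-overflow semantics of the hardware:
#' it accumulates oscillations modulo `2^bits`, and the processor reads the
#' value and resets it to zero at every wake-up.
#'
#' @param bits Counter width in bits.
#' @return A counter object.
#' @export
new_counter <- function(bits = COUNTER_BITS) {
  state <- new.env(parent = emptyenv())
  state$value <- 0
  state$modulus <- 2^bits
  class(state) <- "lux_counter"
  state
}

#' @describeIn new_counter Add `n` oscillations (wraps modulo `2^bits`).
#' @param counter A counter from [new_counter()].
#' @param n Number of oscillations to add.
#' @export
count_up <- function(counter, n = 1) {
  counter$value <- (counter$value + n) %% counter$modulus
  invisible(counter)
}

#' @describeIn new_counter Read the accumulated code and reset the counter.
#' @export
read_and_reset <- function(counter) {
  code <- counter$value
  counter$value <- 0
  code
}

# Time-weighted cumulative integral of a piecewise-constant series sampled at
# `times`; each value holds from its timestamp to the next. Returns a function
# evaluating the integral at arbitrary points inside [min(times), end].
cum_integral_pc <- function(times, values, end) {
  keep <- times < end
  knots <- c(times[keep], end)
  cum <- c(0, cumsum(values[keep] * diff(knots)))
  function(at) stats::approx(knots, cum, xout = at, rule = 2)$y
}

#' Simulate per-interval light-dose codes for one sensor
#'
#' Converts a ground-truth environment series into the raw record stream the
#' logger would store: for every duty-cycle interval the oscillation rate is
#' integrated over time, perturbed by one multiplicative Gaussian noise draw,
#' floored to a whole count, and wrapped modulo 2^24. Temperature and battery
#' codes are the sensor's affine encodings of the interval-mean conditions.
#'
#' @param env Tibble with columns `time_s` (seconds, strictly increasing,
#'   piecewise-constant sampling finer than or equal to the interval), `lux`,
#'   `temp_C`, `vbat_V`.
#' @param params A `sensor_params` row.
#' @param interval_s Duty-cycle interval in seconds (default 600 = 10 min).
#' @param seed Integer seed for the per-interval noise draws.
#' @param t_end Optional end of the recording; defaults to the last
#'   environment timestamp.
#' @return Tibble with one row per complete interval: `sensor_id`, `time_s`
#'   (interval end, when the code is read), `light_code`, `temp_code`,
#'   `vbat_code`.
#' @export
simulate_counts <- function(env, params, interval_s = 600, seed = 1L,
                            t_end = NULL) {
  stopifnot(interval_s > 0)
  if (nrow(env) == 0) {
    warning("empty environment series; returning empty record stream")
    return(tibble::tibble(
      sensor_id = character(), time_s = numeric(),
      light_code = numeric(), temp_code = numeric(), vbat_code = numeric()
    ))
  }
  if (is.unsorted(env$time_s, strictly = TRUE)) {
    stop("`env$time_s` must be strictly increasing", call. = FALSE)
  }
  t0 <- env$time_s[1]
  t_end <- t_end %||% max(env$time_s)
  n_int <- floor((t_end - t0) / interval_s)
  if (n_int < 1) {
    warning("environment does not cover a full interval; empty record stream")
    return(tibble::tibble(
      sensor_id = character(), time_s = numeric(),
      light_code = numeric(), temp_code = numeric(), vbat_code = numeric()
    ))
  }
  edges <- t0 + interval_s * (0:n_int)

  rate <- oscillation_rate(env$lux, env$temp_C, env$vbat_V, params)
  cum_rate <- cum_integral_pc(env$time_s, rate, edges[n_int + 1])
  cum_temp <- cum_integral_pc(env$time_s, env$temp_C, edges[n_int + 1])
  cum_vbat <- cum_integral_pc(env$time_s, env$vbat_V, edges[n_int + 1])

  dose <- diff(cum_rate(edges))
  local_seed(seed)
  eps <- stats::rnorm(n_int, 0, params$noise_cv)
  dose <- pmax(dose * (1 + eps), 0)
  light_code <- floor(dose) %% 2^params$counter_bits

  mean_temp <- diff(cum_temp(edges)) / interval_s
  mean_vbat <- diff(cum_vbat(edges)) / interval_s

  tibble::tibble(
    sensor_id = params$sensor_id,
    time_s = edges[-1],
    light_code = light_code,
    temp_code = round(params$temp_sensor_offset +
                        params$temp_sensor_gain * mean_temp),
    vbat_code = round(1000 * mean_vbat + params$vbat_sensor_offset)
  )
}

#' Constant-conditions environment series
#'
#' Convenience constructor for bench conditions: constant lux, temperature and
#' battery voltage sampled at `step_s` over `duration_s` starting at `t0`.
#'
#' @param lux,temp_C,vbat_V Constant conditions.
#' @param duration_s Length of the series in seconds.
#' @param step_s Sampling step.
#' @param t0 Start time in seconds.
#' @return An environment tibble suitable for [simulate_counts()].
#' @export
constant_env <- function(lux, temp_C = 25, vbat_V = 4.1,
                         duration_s = 600, step_s = 60, t0 = 0) {
  stopifnot(lux >= 0)
  times <- seq(t0, t0 + duration_s, by = step_s)
  tibble::tibble(time_s = times, lux = lux, temp_C = temp_C, vbat_V = vbat_V)
}
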