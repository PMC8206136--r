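# Synthetic solar-ecology generator: ground-truth lux scenarios with the
# statistical structure the analysis assumes — diurnal valley irradiance
# (sun clears the valley walls mid-morning, peaks around midday), leaf-top
# and attenuated under-leaf microhabitats with occasional sunfleck spikes,
# and a cover-seeking predator whose exposure stays under a few hundred lux.
# Every default is a tuning target echoing published summary values, not a
# measurement; see the methods vignette.

#' Diurnal irradiance parameters
#'
#' @param sunrise_over_wall Clock time the sun clears the valley walls
#'   (default 09:20).
#' @param sunset_below_wall Clock time direct light is lost (default 16:30).
#' @param peak_time Time of peak irradiance (default 12:30).
#' @param peak_lux Clear-sky ambient peak (lux).
#' @param cloud_factor Per-day multiplier in (0, 1].
#' @param sunfleck_rate Per-minute probability of a sunfleck spike on a
#'   leaf-top series.
#' @param sunfleck_max Upper bound (lux) for spiked readings.
#' @return A list of class `irradiance_params`.
#' @export
irradiance_params <- function(sunrise_over_wall = "09:20",
                              sunset_below_wall = "16:30",
                              peak_time = "12:30",
                              peak_lux = 60000,
                              cloud_factor = 1,
                              sunfleck_rate = 0.005,
                              sunfleck_max = 71165) {
  out <- list(
    sunrise_s = clock_s(sunrise_over_wall),
    sunset_s = clock_s(sunset_below_wall),
    peak_s = clock_s(peak_time),
    peak_lux = peak_lux, cloud_factor = cloud_factor,
    sunfleck_rate = sunfleck_rate, sunfleck_max = sunfleck_max
  )
  stopifnot(out$sunrise_s < out$peak_s, out$peak_s < out$sunset_s,
            peak_lux > 0, cloud_factor > 0, cloud_factor <= 1)
  class(out) <- "irradiance_params"
  out
}

#' Behavioural / microhabitat parameters
#'
#' @param predator_cap_lux Ceiling (lux) the cover-seeking predator tolerates.
#' @param n_cover_cycles Rise-fall cover oscillations between wall-clear and
#'   the midday peak.
#' @param cover_floor Residual exposure fraction right after the peak (deep
#'   cover decays from here towards 0 lux).
#' @param cover_decay_s Time constant of the post-peak deep-cover decay.
#' @param cap_frac_range Per-individual tolerated fraction of the cap
#'   (uniform draw), keeping every individual strictly below the cap.
#' @param under_leaf_atten_shape Beta shape parameters of the under-leaf
#'   attenuation draw on (0, 1); the default mean ~0.49 puts under-leaf
#'   midday means near 4.4 klux when leaf tops run near 9 klux.
#' @param leaf_top_exposure_mean,leaf_top_exposure_sdlog Lognormal per-plant
#'   exposure multiplier (mean fraction of open-sky ambient reaching the
#'   leaf).
#' @param reading_noise_sdlog Lognormal per-reading noise on prey series.
#' @param predator_noise_sdlog Lognormal per-reading noise on predator
#'   series.
#' @param spike_rate Per-minute probability of an open-trail spike on a
#'   predator series (default 0: disabled).
#' @param spike_max Upper bound (lux) for predator spike readings.
#' @param group_log_effects Nominal log10-scale category effects implied by
#'   the defaults, used by model-level power studies.
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(predator_cap_lux = 900,
                            n_cover_cycles = 3,
                            cover_floor = 0.03,
                            cover_decay_s = 3600,
                            cap_frac_range = c(0.4, 0.95),
                            under_leaf_atten_shape = c(4, 4.2),
                            leaf_top_exposure_mean = 0.15,
                            leaf_top_exposure_sdlog = 0.5,
                            reading_noise_sdlog = 0.35,
                            predator_noise_sdlog = 0.4,
                            spike_rate = 0,
                            spike_max = 13449,
                            group_log_effects = c(leaf_top = 0,
                                                  under_leaf = -0.31,
                                                  predator = -1.2)) {
  stopifnot(predator_cap_lux > 0, n_cover_cycles >= 1,
            all(cap_frac_range > 0), all(cap_frac_range < 1),
            leaf_top_exposure_mean > 0)
  structure(as.list(environment()), class = "behavior_params")
}

#' Study design: group sizes, sites, days, sampling
#'
#' Defaults follow the field layout: 41 leaf-top and 40 under-leaf series at
#' three prey sites over four days, 37 predators at two sites over four
#' days, 26 under-leaf individuals carrying two bracketing sensors, 10-min
#' sampling.
#'
#' @param n_leaf_top,n_under_leaf,n_predator Group sizes.
#' @param n_paired_under_leaf Under-leaf individuals with two sensors.
#' @param interval_s Duty-cycle sampling interval (seconds).
#' @param seed Integer seed (mandatory).
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_leaf_top = 41, n_under_leaf = 40,
                         n_predator = 37, n_paired_under_leaf = 26,
                         interval_s = 600, seed) {
  stopifnot(n_leaf_top >= 1, n_under_leaf >= 1, n_predator >= 1,
            n_under_leaf <= n_leaf_top,
            n_paired_under_leaf <= n_under_leaf, !missing(seed))
  structure(
    list(n_leaf_top = n_leaf_top, n_under_leaf = n_under_leaf,
         n_predator = n_predator,
         n_paired_under_leaf = n_paired_under_leaf,
         interval_s = interval_s, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Ambient valley irradiance at clock time t
#'
#' Zero before the sun clears the valley walls and after it drops below
#' them; in between, an asymmetric half-cosine peaking at `peak_time`:
#' `peak_lux * cloud_factor * cos(pi/2 * (t - peak) / half_width)` with the
#' half-width taken on each side of the peak.
#'
#' @param t_s Clock time(s) in seconds since midnight (vectorised).
#' @param irr An [irradiance_params()] object.
#' @return Illuminance in lux.
#' @export
ambient_irradiance <- function(t_s, irr = irradiance_params()) {
  t_s <- clock_s(t_s)
  w_am <- irr$peak_s - irr$sunrise_s
  w_pm <- irr$sunset_s - irr$peak_s
  u <- ifelse(t_s <= irr$peak_s, (t_s - irr$peak_s) / w_am,
              (t_s - irr$peak_s) / w_pm)
  lux <- irr$peak_lux * irr$cloud_factor * cos(pi / 2 * pmin(abs(u), 1))
  ifelse(t_s < irr$sunrise_s | t_s > irr$sunset_s, 0, pmax(lux, 0))
}

#' @describeIn ambient_irradiance Closed-form integral of the daily curve
#'   (lux-seconds), for quadrature checks.
#' @param irr An [irradiance_params()] object.
#' @export
ambient_integral <- function(irr = irradiance_params()) {
  (2 / pi) * irr$peak_lux * irr$cloud_factor * (irr$sunset_s - irr$sunrise_s)
}

day_times <- function(start = "08:30", end = "16:30", step_s = 60) {
  seq(clock_s(start), clock_s(end), by = step_s)
}

#' Generate one leaf-top ground-truth lux series
#'
#' `ambient x per-plant exposure x lognormal reading noise`, plus a sunfleck
#' marked point process with uniform marks, the whole series bounded by
#' `sunfleck_max`.
#'
#' @param irr,behav Parameter objects.
#' @param exposure Per-plant exposure multiplier; drawn from the lognormal
#'   default when `NULL`.
#' @param noise Apply reading noise and sunflecks? `FALSE` gives the
#'   deterministic `ambient x exposure` curve.
#' @param seed Seed.
#' @param step_s Truth-series resolution (seconds).
#' @param start,end Clock bounds of the series.
#' @return Tibble (`time_s`, `lux`) with the exposure as an attribute.
#' @export
gen_leaf_top <- function(irr = irradiance_params(),
                         behav = behavior_params(),
                         exposure = NULL, noise = TRUE, seed = 1L,
                         step_s = 60, start = "08:30", end = "16:30") {
  t_s <- day_times(start, end, step_s)
  local_seed(seed)
  if (is.null(exposure)) {
    sdl <- behav$leaf_top_exposure_sdlog
    exposure <- stats::rlnorm(1, log(behav$leaf_top_exposure_mean) -
                                sdl^2 / 2, sdl)
  }
  lux <- ambient_irradiance(t_s, irr) * exposure
  if (noise) {
    sdl <- behav$reading_noise_sdlog
    lux <- lux * stats::rlnorm(length(t_s), -sdl^2 / 2, sdl)
    lit <- lux > 0
    fleck <- lit & stats::runif(length(t_s)) < irr$sunfleck_rate
    if (any(fleck)) {
      lux[fleck] <- pmin(lux[fleck] +
                           stats::runif(sum(fleck), 0, irr$sunfleck_max),
                         irr$sunfleck_max)
    }
    lux <- pmin(lux, irr$sunfleck_max)
  }
  out <- tibble::tibble(time_s = t_s, lux = lux)
  attr(out, "exposure") <- exposure
  out
}

#' Generate an under-leaf series from its plant's leaf-top series
#'
#' The under-leaf microhabitat sees the same plant's light attenuated by a
#' per-sensor Beta-distributed factor in (0, 1), so it never exceeds the
#' leaf top pointwise.
#'
#' @param leaf_top A [gen_leaf_top()] series.
#' @param behav Behaviour parameters.
#' @param attenuation Attenuation in (0, 1); drawn when `NULL`.
#' @param seed Seed for the draw.
#' @return Tibble (`time_s`, `lux`) with the attenuation as an attribute.
#' @export
gen_under_leaf <- function(leaf_top, behav = behavior_params(),
                           attenuation = NULL, seed = 1L) {
  if (is.null(attenuation)) {
    local_seed(seed)
    attenuation <- stats::rbeta(1, behav$under_leaf_atten_shape[1],
                                behav$under_leaf_atten_shape[2])
  }
  stopifnot(attenuation > 0, attenuation <= 1)
  out <- tibble::tibble(time_s = leaf_top$time_s,
                        lux = leaf_top$lux * attenuation)
  attr(out, "attenuation") <- attenuation
  out
}

#' Generate one cover-seeking predator series
#'
#' Exposure is `min(ambient, individual cap) x cover(t)`: between wall-clear
#' and the midday peak, cover oscillates through `n_cover_cycles` rise-fall
#' cycles (the animal repeatedly ventures out and retreats as irradiance
#' grows); after the peak it stays in deep cover, decaying from
#' `cover_floor` towards 0 lux. Absent spike events the series never reaches
#' `predator_cap_lux`.
#'
#' @param irr,behav Parameter objects.
#' @param cap_frac Individual tolerated fraction of the cap; drawn uniform
#'   from `behav$cap_frac_range` when `NULL`.
#' @param noise Apply lognormal reading noise (still capped)?
#' @param spikes Allow open-trail spike events at `behav$spike_rate`?
#' @param seed Seed.
#' @param step_s,start,end Series resolution and clock bounds.
#' @return Tibble (`time_s`, `lux`).
#' @export
gen_predator <- function(irr = irradiance_params(),
                         behav = behavior_params(),
                         cap_frac = NULL, noise = TRUE, spikes = TRUE,
                         seed = 1L, step_s = 60,
                         start = "08:30", end = "16:30") {
  t_s <- day_times(start, end, step_s)
  local_seed(seed)
  if (is.null(cap_frac)) {
    cap_frac <- stats::runif(1, behav$cap_frac_range[1],
                             behav$cap_frac_range[2])
  }
  cap_i <- behav$predator_cap_lux * cap_frac
  amb <- ambient_irradiance(t_s, irr)
  avail <- pmin(amb, cap_i)
  u <- (t_s - irr$sunrise_s) / (irr$peak_s - irr$sunrise_s)
  cover <- numeric(length(t_s))
  pre <- t_s >= irr$sunrise_s & t_s <= irr$peak_s
  post <- t_s > irr$peak_s
  cover[pre] <- 0.5 * (1 - cos(2 * pi * behav$n_cover_cycles * u[pre]))
  cover[post] <- behav$cover_floor *
    exp(-(t_s[post] - irr$peak_s) / behav$cover_decay_s)
  lux <- avail * cover
  if (noise) {
    sdl <- behav$predator_noise_sdlog
    lux <- pmin(lux * stats::rlnorm(length(t_s), -sdl^2 / 2, sdl), cap_i)
  }
  if (spikes && behav$spike_rate > 0) {
    lit <- amb > 0
    sp <- lit & stats::runif(length(t_s)) < behav$spike_rate
    if (any(sp)) {
      lux[sp] <- pmin(lux[sp] + stats::runif(sum(sp), 0, behav$spike_max),
                      behav$spike_max)
    }
  }
  out <- tibble::tibble(time_s = t_s, lux = lux)
  attr(out, "cap_i") <- cap_i
  out
}

# Site/day layout echoing the field campaign; recycled if group sizes differ
# from the defaults.
prey_layout <- function(n) {
  base <- tibble::tibble(
    site = rep(c("tipaerui_iti", "tipaerui_iti", "faarapa", "matatia"),
               c(12, 16, 6, 7)),
    date = as.Date(rep(c("2017-08-10", "2017-08-15", "2017-08-05",
                         "2017-08-07"), c(12, 16, 6, 7)))
  )
  base[rep_len(seq_len(nrow(base)), n), ]
}

predator_layout <- function(n) {
  base <- tibble::tibble(
    site = rep(c("fautaua_iti", "fautaua_iti", "fautaua", "fautaua"),
               c(5, 4, 12, 16)),
    date = as.Date(rep(c("2017-08-08", "2017-08-11", "2017-08-12",
                         "2017-08-14"), c(5, 4, 12, 16)))
  )
  base[rep_len(seq_len(nrow(base)), n), ]
}

#' Generate a complete synthetic field study
#'
#' Emits everything the downstream pipeline consumes: per-sensor ground-truth
#' lux series, deployment metadata (with two bracketing sensors for a subset
#' of under-leaf individuals), per-sensor hardware parameters drawn from the
#' fabrication-spread model, and — unless `sensors = FALSE` — the simulated
#' raw counter records for every sensor, plus four reference sensors for
#' model building. Identical seeds reproduce identical output.
#'
#' @param design A [study_design()] (its `seed` drives everything).
#' @param irr,behav Parameter objects.
#' @param sensors Simulate the hardware layer (sensor draws + raw records)?
#'   `FALSE` returns truth series and metadata only.
#' @return A list of class `field_study`: `truth` (sensor_id, individual,
#'   category, time_s, lux), `deployments`, `sensors`, `reference_sensors`,
#'   `records`, and the generating parameter objects.
#' @export
gen_field_study <- function(design = study_design(seed = 1L),
                            irr = irradiance_params(),
                            behav = behavior_params(),
                            sensors = TRUE) {
  seed <- design$seed
  n_lt <- design$n_leaf_top; n_ul <- design$n_under_leaf
  n_pr <- design$n_predator
  prey_sites <- prey_layout(n_lt)
  pred_sites <- predator_layout(n_pr)

  truth <- list(); deployments <- list()
  sensor_counter <- 0
  next_sensor <- function() {
    sensor_counter <<- sensor_counter + 1
    sprintf("fs_%03d", sensor_counter)
  }

  # leaf-top series double as the ambient input for the under-leaf snails on
  # the same plant
  leaf_series <- vector("list", n_lt)
  for (i in seq_len(n_lt)) {
    leaf_series[[i]] <- gen_leaf_top(irr, behav, seed = child_seed(seed, i))
    sid <- next_sensor()
    ind <- sprintf("plant_%02d", i)
    truth[[length(truth) + 1]] <- tibble::tibble(
      sensor_id = sid, individual = ind, category = "leaf_top",
      time_s = leaf_series[[i]]$time_s, lux = leaf_series[[i]]$lux
    )
    deployments[[length(deployments) + 1]] <- deployment(
      ind, "leaf_top", prey_sites$site[i], prey_sites$date[i], sid
    )
  }
  for (i in seq_len(n_ul)) {
    ind <- sprintf("snail_%02d", i)
    n_sens <- if (i <= design$n_paired_under_leaf) 2 else 1
    sids <- character(n_sens)
    for (k in seq_len(n_sens)) {
      ul <- gen_under_leaf(leaf_series[[i]], behav,
                           seed = child_seed(seed, 1000 + 10 * i + k))
      sids[k] <- next_sensor()
      truth[[length(truth) + 1]] <- tibble::tibble(
        sensor_id = sids[k], individual = ind, category = "under_leaf",
        time_s = ul$time_s, lux = ul$lux
      )
    }
    deployments[[length(deployments) + 1]] <- deployment(
      ind, "under_leaf", prey_sites$site[i], prey_sites$date[i], sids
    )
  }
  for (i in seq_len(n_pr)) {
    pr <- gen_predator(irr, behav, seed = child_seed(seed, 2000 + i))
    sid <- next_sensor()
    ind <- sprintf("predator_%02d", i)
    truth[[length(truth) + 1]] <- tibble::tibble(
      sensor_id = sid, individual = ind, category = "predator",
      time_s = pr$time_s, lux = pr$lux
    )
    deployments[[length(deployments) + 1]] <- deployment(
      ind, "predator", pred_sites$site[i], pred_sites$date[i], sid
    )
  }
  truth <- dplyr::bind_rows(truth)
  deployments <- dplyr::bind_rows(deployments)

  out <- list(truth = truth, deployments = deployments,
              design = design, irr = irr, behav = behav,
              sensors = NULL, reference_sensors = NULL, records = NULL)
  if (sensors) {
    sensor_ids <- unique(truth$sensor_id)
    batch <- draw_sensor_batch(length(sensor_ids),
                               seed = child_seed(seed, 9001))
    batch$sensor_id <- sensor_ids
    out$sensors <- batch
    out$reference_sensors <- draw_sensor_batch(
      4, seed = child_seed(seed, 9002), id_prefix = "ref", noise_cv = 0
    )
    out$records <- purrr::map_dfr(seq_along(sensor_ids), function(j) {
      tr <- truth[truth$sensor_id == sensor_ids[j], ]
      env <- tibble::tibble(
        time_s = tr$time_s, lux = tr$lux,
        # mild diurnal temperature swing and slow battery sag
        temp_C = 26 + 4 * sin(pi * (tr$time_s - 30600) / 28800),
        vbat_V = 4.15 - 0.1 * (tr$time_s - min(tr$time_s)) /
          diff(range(tr$time_s))
      )
      simulate_counts(env, batch[j, ], interval_s = design$interval_s,
                      seed = child_seed(seed, 3000 + j))
    })
  }
  structure(out, class = "field_study")
}

#' @export
print.field_study <- function(x, ...) {
  cat("<field_study> synthetic solar-ecology study\n")
  cat(sprintf("  %d individuals (%d leaf_top / %d under_leaf / %d predator), %d sensor streams\n",
              nrow(x$deployments), x$design$n_leaf_top,
              x$design$n_under_leaf, x$design$n_predator,
              length(unique(x$truth$sensor_id))))
  cat(sprintf("  raw records: %s\n",
              if (is.null(x$records)) "not simulated"
              else paste0(nrow(x$records), " rows")))
  invisible(x)
}
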