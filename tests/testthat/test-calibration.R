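test_that("characterisation covers the factorial grid", {
  fx <- ref_model_fixture()
  # 6 light levels x 4 temperatures x 4 voltages = 96 cells per sensor
  counts <- dplyr::count(fx$grid, sensor_id)
  expect_equal(nrow(fx$grid), 4 * 96)
  expect_true(all(counts$n == 96))
  # degenerate single-cell axes
  one <- characterize(reference_sensor(),
                      axes = list(light_klux = 5, temp_C = 25, vbat_V = 4.1))
  expect_equal(nrow(one), 1)
  # noiseless characterisation is deterministic
  again <- characterize(fx$sensors)
  expect_identical(fx$grid, again)
  expect_error(characterize(reference_sensor(), axes = list(light_klux = 5)),
               "axes")
})

test_that("global model averages reference codes cellwise", {
  # four identical grids: model equals any one grid
  m <- nominal_model_fixture()
  g1 <- characterize(reference_sensor())
  expect_equal(as.vector(m$codes),
               g1$light_code[order(g1$vbat_V, g1$temp_C, g1$light_klux)])
  # cell mean: hand-built two-level grids with codes 100/110/90/100 -> 100
  fake <- purrr::map_dfr(1:4, function(i) {
    tibble::tibble(sensor_id = paste0("f", i), light_klux = c(0.5, 1),
                   temp_C = 25, vbat_V = 4.1,
                   light_code = c(c(100, 110, 90, 100)[i],
                                  c(200, 220, 180, 200)[i]),
                   temp_code = 250, vbat_code = 4100)
  })
  mf <- build_global_model(fake)
  expect_equal(as.vector(mf$codes), c(100, 200))
  # model evaluated at a grid node returns the averaged node code exactly
  fx <- ref_model_fixture()
  at_node <- model_codes_at(fx$model, 35, 4.0)
  expect_equal(at_node, unname(fx$model$codes[, "35", "4"]))
  # incomplete grids are rejected
  expect_error(build_global_model(fake[-1, ]), "full factorial")
})

test_that("per-sensor calibration recovers gain, offset and temperature map", {
  m <- nominal_model_fixture()
  ref <- reference_sensor()
  cal <- calibrate_sensor(ref, m)
  # a sensor identical to the reference mean needs no correction
  expect_equal(cal$light_gain, 1)
  expect_equal(cal$vbat_offset, 0)
  expect_equal(decode_temp(cal$temp_code_anchors[[1]], cal), c(25, 45, 55))
  # a sensor running at twice the reference rate (gain and dark rate both
  # doubled) produces codes twice the reference and inverts to gain 1/2
  dbl <- sensor_params("dbl", gain = 0.4, dark_rate = 16, noise_cv = 0)
  cal2 <- calibrate_sensor(dbl, m)
  expect_equal(cal2$light_gain, 0.5)
  # pure gain distortion g is identified as light_gain = 1/g exactly
  g <- 1.6
  gs <- sensor_params("g", gain = 0.2 * g, dark_rate = 8 * g, noise_cv = 0)
  calg <- calibrate_sensor(gs, m)
  expect_equal(calg$light_gain, 1 / g, tolerance = 1e-12)
  expect_error(calibrate_sensor(ref, m, cal_temps_C = c(25, 45)),
               "3 anchor")
})

test_that("temperature decoding interpolates the three anchors", {
  cal <- tibble::tibble(sensor_id = "x",
                        temp_C_anchors = list(c(25, 45, 55)),
                        temp_code_anchors = list(c(10, 30, 40)),
                        light_gain = 1, vbat_offset = 0)
  expect_equal(decode_temp(30, cal), 45)
  expect_equal(decode_temp(20, cal), 35)
  expect_equal(decode_temp(35, cal), 50)
  # linear extrapolation beyond the anchors
  expect_equal(decode_temp(0, cal), 15)
  expect_equal(decode_temp(44, cal), 59)
})

test_that("code-to-lux inversion is the identity at grid nodes", {
  fx <- ref_model_fixture()
  m <- fx$model
  cells <- tidyr::crossing(light_klux = m$axes$light_klux,
                           temp_C = m$axes$temp_C, vbat_V = m$axes$vbat_V)
  rec <- tibble::tibble(
    light_code = purrr::pmap_dbl(cells, function(light_klux, temp_C, vbat_V) {
      m$codes[as.character(light_klux), as.character(temp_C),
              as.character(vbat_V)]
    }),
    temp_code = interp_extrap(m$temp_ref$temp_C, m$temp_ref$code,
                              cells$temp_C),
    vbat_code = interp_extrap(m$vbat_ref$vbat_V, m$vbat_ref$code,
                              cells$vbat_V)
  )
  out <- codes_to_lux(rec, identity_calibration(m), m)
  rel_err <- abs(out$lux - 1000 * cells$light_klux) / (1000 * cells$light_klux)
  # exact at the calibration anchor temperatures; elsewhere bounded by the
  # one-count quantisation of the temperature/voltage encodings
  expect_lt(max(rel_err[cells$temp_C %in% c(25, 45, 55)]), 1e-10)
  expect_lt(max(rel_err), 1e-3)
})

test_that("recovered lux is monotone in the light code", {
  fx <- ref_model_fixture()
  codes <- sort(c(0, 10, 1e3, 1e4, 1e5, 5e5, 1e6, 5e6, 1e7, 1.5e7))
  rec <- tibble::tibble(
    light_code = codes,
    temp_code = interp_extrap(fx$model$temp_ref$temp_C,
                              fx$model$temp_ref$code, rep(30, length(codes))),
    vbat_code = interp_extrap(fx$model$vbat_ref$vbat_V,
                              fx$model$vbat_ref$code, rep(4.05, length(codes)))
  )
  out <- codes_to_lux(rec, identity_calibration(fx$model), fx$model)
  expect_false(is.unsorted(out$lux))
  expect_true(all(out$lux >= 0))
})

test_that("off-grid round trip stays within the interpolation budget", {
  # noiseless reference-like sensor measured off every grid axis
  m <- nominal_model_fixture()
  s <- reference_sensor("offgrid")
  cal <- calibrate_sensor(s, m)
  env <- constant_env(7000, temp_C = 30, vbat_V = 4.05, duration_s = 600)
  rec <- simulate_counts(env, s, interval_s = 600)
  out <- codes_to_lux(rec, cal, m)
  # the only error source is piecewise-log-linear interpolation of the
  # affine response across the 5-10 klux octave; measure that envelope by
  # brute-force forward simulation over the segment and require the
  # round-trip error to sit inside it (and the envelope itself to be small)
  envelope <- max(vapply(seq(5000, 10000, by = 250), function(lux_true) {
    r <- simulate_counts(constant_env(lux_true, temp_C = 30, vbat_V = 4.05,
                                      duration_s = 600), s,
                         interval_s = 600)
    abs(codes_to_lux(r, cal, m)$lux - lux_true) / lux_true
  }, numeric(1)))
  expect_lte(abs(out$lux - 7000) / 7000, envelope)
  expect_lt(envelope, 0.10)
  # and a below-grid reading inverts through the dark-origin segment
  env_lo <- constant_env(200, duration_s = 600)
  rec_lo <- simulate_counts(env_lo, s, interval_s = 600)
  out_lo <- codes_to_lux(rec_lo, cal, m)
  expect_lt(abs(out_lo$lux - 200) / 200, 0.05)
})

test_that("calibration reduces batch spread; stability meets the bench bound", {
  fx <- ref_model_fixture()
  for (seed in c(42, 43)) {
    batch <- draw_sensor_batch(8, seed = seed)
    v_cal <- validate_batch(batch, fx$model, seed = seed + 100)
    v_raw <- validate_batch(batch, fx$model, seed = seed + 100,
                            calibrated = FALSE)
    # calibration strictly reduces the worst-case sigma/mean
    expect_lt(worst_cv(v_cal), worst_cv(v_raw))
    # worst-case stability within the printed bench bound
    expect_lte(worst_cv(v_cal), 0.28)
    # nonlinearity ratio within the printed range
    expect_true(all(v_cal$nonlin >= -0.37 & v_cal$nonlin <= 0.14))
    expect_equal(nrow(v_cal), 9)
  }
  # identical sensors: no spread at all (noise off)
  twins <- purrr::map_dfr(1:3, function(i) reference_sensor(paste0("t", i)))
  v0 <- validate_batch(twins, nominal_model_fixture(), noise = FALSE)
  expect_true(all(v0$cv < 1e-12))
})
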