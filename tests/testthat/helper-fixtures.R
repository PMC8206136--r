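# Shared fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

# Four-sensor reference characterisation and the resulting global model.
ref_model_fixture <- function() {
  if (is.null(.fixtures$ref_model)) {
    refs <- draw_sensor_batch(4, seed = 11, id_prefix = "ref", noise_cv = 0)
    grid <- characterize(refs)
    .fixtures$ref_sensors <- refs
    .fixtures$ref_grid <- grid
    .fixtures$ref_model <- build_global_model(grid)
  }
  list(sensors = .fixtures$ref_sensors, grid = .fixtures$ref_grid,
       model = .fixtures$ref_model)
}

# A model built from four identical copies of the nominal noiseless sensor,
# so the averaged reference equals that sensor exactly.
nominal_model_fixture <- function() {
  if (is.null(.fixtures$nominal_model)) {
    refs <- purrr::map_dfr(1:4, function(i) {
      s <- reference_sensor(sprintf("nom_%d", i))
      s
    })
    .fixtures$nominal_model <- build_global_model(characterize(refs))
  }
  .fixtures$nominal_model
}

# Small processed synthetic study shared across pipeline tests.
small_study_fixture <- function() {
  if (is.null(.fixtures$small_study)) {
    design <- study_design(n_leaf_top = 5, n_under_leaf = 4, n_predator = 4,
                           n_paired_under_leaf = 2, seed = 21)
    st <- gen_field_study(design)
    .fixtures$small_study <- list(study = st, processed = process_study(st))
  }
  .fixtures$small_study
}

# Constant-rate sensor helpers.
noiseless_sensor <- function(id = "s", gain = 0.2, dark_rate = 0, ...) {
  sensor_params(id, gain = gain, dark_rate = dark_rate, noise_cv = 0,
                temp_coeff = 0, vbat_coeff = 0, ...)
}
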