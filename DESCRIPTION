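Package: luxdose
Title: Duty-Cycled Light-Dose Sensor Simulation, Calibration, and
    Solar-Exposure Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates miniature energy-harvesting light loggers that
    integrate illuminance into per-interval counter codes, reconstructs lux
    from those codes via grid characterization and per-sensor three-point /
    one-point calibration, bins field recordings into a tidy analysis table,
    and compares exposure groups with a repeated-measures linear mixed model
    (random individual intercepts, AR(1) within-individual correlation,
    REML) followed by Wald chi-square ANOVA and Tukey-adjusted contrasts.
    Includes a synthetic solar-ecology generator emulating tropical valley
    irradiance, leaf-top and under-leaf microhabitats, and cover-seeking
    predator behaviour, so the full measurement-to-inference chain is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    hms,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    emmeans,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
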