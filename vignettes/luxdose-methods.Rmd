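---
title: "From counter codes to contrasts: the luxdose measurement and inference chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From counter codes to contrasts: the luxdose measurement and inference chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

luxdose simulates and analyses data from miniature energy-harvesting light
loggers of the kind used to compare the daily solar exposure of animals in
the field — here, aestivating prey snails on forest-edge foliage versus an
actively foraging predator snail. This vignette is the package's own account
of the models it implements, the parameters that matter, and the design
choices made where the design was genuinely open.

## 1. The sensor model

The logger harvests energy from a photovoltaic cell through a switched-
capacitor up-converter whose ring-oscillator frequency tracks the PV
current, and the PV current tracks illuminance. A low-power counter
accumulates oscillations during each 10-minute sleep interval; at wake-up
the processor reads the counter — the *light-dose code* — and resets it.
The counter is 24 bits wide, so stored codes wrap modulo $2^{24}$.

`oscillation_rate()` implements the first-order behavioural law

$$f(L, T, V) = (d + gL)\,\bigl(1 + c_T (T - 25)\bigr)\,\bigl(1 + c_V (V - 4.1)\bigr),$$

with $L$ illuminance (lux), $g$ the gain (osc/s/lux), $d$ the dark rate
(osc/s), and fractional temperature and battery-voltage coefficients $c_T$
(per °C from 25 °C) and $c_V$ (per V from 4.1 V), clamped at zero. The law
is deliberately minimal: the physical statement is proportionality to first
order, and the calibration stage exists precisely to absorb what the law
leaves out. `simulate_counts()` integrates $f$ over each interval,
multiplies by one Gaussian factor $1 + \varepsilon$ per interval
($\varepsilon \sim N(0, \text{noise\_cv}^2)$ — the coefficient of variation
is the natural stability metric for these readings), floors to a whole
count, and wraps. Temperature and battery codes are affine encodings of
interval means with per-sensor distortion, rounded to integer codes.

Two semantics were possible for the counter: reset-at-read (per-interval
dose codes) or free-running with differencing. Reset-at-read is implemented,
matching the read-then-reset processor behaviour; the two differ only in
how wraparound presents.

## 2. Characterisation and calibration

Four reference sensors are measured over a full factorial grid — light
0.5, 1, 5, 10, 50, 100 klux; temperature 25, 35, 45, 55 °C; battery 3.9,
4.0, 4.1, 4.2 V; 96 cells per sensor (`characterize()`). Averaging the
light codes cellwise gives the global piecewise-linear code→lux model
(`build_global_model()`).

Each deployed sensor then receives (`calibrate_sensor()`):

* a **three-point temperature calibration**: its temperature codes at 25,
  45 and 55 °C anchor a piecewise-linear code→°C map;
* a **one-point light calibration**: the ratio of the reference code to the
  sensor's code at 5 klux / 25 °C / 4.1 V becomes a multiplicative
  `light_gain`;
* a **one-point battery calibration**: an additive code offset at 4.1 V.

The light anchor's temperature is not dictated by the calibration protocol
itself (three temperatures are visited); 25 °C is used because it is the
one condition shared by all three calibrations.

`codes_to_lux()` inverts the chain per record: decode temperature and
voltage, scale the light code by `light_gain`, interpolate the global model
bilinearly over (temperature, voltage) to get the six reference codes at
the decoded conditions, and invert the monotone light axis by piecewise
linear interpolation. Interpolation on the light axis is done in
$\log_{10}$ lux by default because the grid spans 2.3 decades with
near-geometric spacing; linear-space interpolation is selectable
(`interp = "linear"`). Whether the "piecewise linear model" should run
codes→lux directly or lux→codes-then-invert was open; inversion of the
forward map is used because it is exact at grid nodes by construction.

Degenerate regions are handled explicitly: codes below the 0.5-klux node
follow a linear segment through the extrapolated dark-code origin (the
intersection of the two lowest nodes' segment with 0 lux), floored at
0 lux; codes above the 100-klux node extrapolate the top segment. Decoded
temperatures or voltages outside a broad plausibility window flag the
record (`suspect`) but keep its value.

Because all on-board codes are integer-quantised, the
characterise→average→invert chain is the identity at grid nodes only up to
quantisation: exact (to floating point) at the calibration anchor
temperatures, and within about $10^{-3}$ relative elsewhere on the grid.
The tests assert both bounds.

### Fabrication spread

No distributional information exists for sensor-to-sensor variation, so
`draw_sensor_batch()` adopts assumptions, chosen once: gain lognormal
around 0.2 osc/s/lux with 25% log-sd; dark rate Gamma (mean 8, sd 4
osc/s); temperature coefficient $N(-0.002, 0.004)$ /°C; battery
coefficient $N(0.10, 0.05)$ /V; per-interval noise CV 5%; Gaussian
distortions of the temperature/voltage encodings. Under these defaults the
*uncalibrated* batch spread is dominated by the ~25% gain spread —
echoing the printed worst-case bench figure of σ/µ = 28% — while
calibration removes the gain component and leaves residuals from the
temperature-coefficient spread, dark-rate spread (visible at 0.5 klux) and
read noise, typically 5–13%. `validate_batch()` measures exactly this.

## 3. Field pipeline

The analysis window is 09:30–16:00 local time. A reading stamped at clock
tick $t$ integrates $(t - 10\,\text{min}, t]$, and the tick grid 09:30,
09:40, …, 16:00 contains exactly 40 ticks — the only convention under
which a full day yields 40 timepoints. Tahiti keeps no daylight saving, so
clock time is plain civil time throughout. `align_and_trim()` keeps
readings whose tick lies on the grid and inside the deployment's
meaningful-measurement window, and counts every exclusion so binning
conserves records.

Under-leaf individuals may carry two bracketing sensors;
`pair_average()` takes the binwise mean (bins present in one series only
are used as-is and flagged). `build_tidy_table()` assembles the long
(individual, category, time_bin, lux) table; missing bins stay absent —
they are excluded from analysis, never zero-filled or imputed, mirroring
the `na.exclude` missing-data rule of the inference stage.
`summarize_light()`, `fold_difference()` and `exceedance()` produce the
descriptive outputs (mean ± SE, boxplot five-number summaries with
1.5×IQR whiskers, ratios of category means, and threshold-exceedance
fractions such as the share of readings above 3000 lux).

## 4. The repeated-measures model

Raw lux values are heavily right-skewed (the Shapiro–Wilk screen,
`normality_screen()`, rejects normality emphatically on any realistic
scenario), so the response is $y = \log_{10}(\text{lux} + 1)$. The base
and the zero-handling offset were open choices: base 10 only rescales
coefficients, and the +1 offset keeps $y(0) = 0$ on a measurement range
where true zeros occur. Both are arguments (`log_base`, `offset`).

`fit_lmm_ar1()` fits, by REML,

$$y_{it} = \beta_0 + \beta_g + \beta_t\, t + \beta_{gt}\, t + b_i + e_{it},
\qquad b_i \sim N(0, \tau^2),$$

with group $g$ a three-level factor, time $t$ the continuous 0-based bin
index (0–39), a random intercept per individual, and AR(1) within-
individual errors: $\mathrm{Cov}(e_{it}, e_{is}) = \sigma^2
\phi^{|t-s|}$. Time enters continuously because the factor-level
alternative would consume 39 degrees of freedom where the target analysis
spends 1. Gaps from missing bins are handled naturally by the $\phi^{|t -
s|}$ decay.

The REML criterion is maximised over $(\log \tau^2, \log \sigma^2,
\operatorname{artanh} \phi)$ — an unconstrained smooth parameterisation —
with $\beta$ profiled out by generalised least squares at each candidate,
using a bounded quasi-Newton optimiser from a moment-based start plus two
jittered restarts (fixed seed). Individuals sharing a time grid and design
block are pooled so each likelihood evaluation performs one Cholesky
factorisation per pool; balanced data collapses to three pools and a fit
takes a fraction of a second at the full design. $|\phi|$ is bounded at
0.995 and a boundary estimate triggers a warning; non-convergence on all
starts raises an error carrying the best-so-far state.

The fitter is validated two independent ways in the test suite: against a
deliberately naive dense-matrix implementation of the closed-form
restricted likelihood on tiny instances (agreement to $10^{-8}$), and
against a reference mixed-model implementation (`nlme::lme` with AR(1)
correlation) on moderate instances.

`wald_anova()` produces the factor table from the fixed-effect estimates
and covariance. Type II is the default (each term tested after all others
except those containing it, via differences of nested Wald statistics),
matching the convention of the standard ANOVA command for mixed models;
Type III is selectable. Degrees of freedom are fixed by the design: 2
(Group), 1 (Time), 2 (Group × Time).

`tukey_contrasts()` compares the three groups at the observed mean of the
time covariate — with the interaction present this evaluation point
matters, and the mean of the observed bins is the least arbitrary choice;
`at_time` overrides it. Standard errors come from the fixed-effect
covariance, degrees of freedom follow the containment rule
$n_{\text{individuals}} - n_{\text{groups}}$ (118 individuals give
DF = 115), and familywise adjustment uses the studentized-range
distribution with three means. A Wald z table and a one-row model summary
are available through `tidy()` and `glance()`.

## 5. The synthetic scenario generator

`gen_field_study()` emulates the statistical structure the analysis
assumes, not the optics of a real valley:

* **Ambient irradiance** (`ambient_irradiance()`): zero until the sun
  clears the valley walls (09:20), an asymmetric half-cosine peaking at
  12:30 (clear-sky peak 60 klux by default), zero after 16:30. A clipped
  sine would serve equally; the half-cosine was chosen for its closed-form
  integral, which the tests use for quadrature checks.
* **Leaf-top series**: ambient × a lognormal per-plant exposure multiplier
  (mean 0.15, log-sd 0.5) × lognormal reading noise (log-sd 0.35), plus a
  sunfleck marked point process (per-minute rate 0.005, uniform marks)
  bounded at 71,165 lux. The defaults are tuning targets: they put the
  midday (12:10–12:50) group mean of a 41-plant batch near 9 klux.
* **Under-leaf series**: the same plant's leaf-top series times a
  Beta(4, 4.2) attenuation (mean ≈ 0.49, midday means ≈ 4.4 klux), so
  under-leaf never exceeds leaf-top pointwise.
* **Predator series**: exposure = min(ambient, individual cap) × a cover
  function with three rise–fall cycles between wall-clearing and the
  midday peak, then deep cover decaying to ~0 lux — a phenomenological
  rendering of cover-seeking (the animal's light exposure was measured,
  not its position). Individual caps are uniform fractions (0.4–0.95) of
  the 900-lux tolerance ceiling, so absent spike events no reading reaches
  900 lux; optional open-trail spikes are bounded at 13,449 lux and
  disabled by default.
* **Design**: 41 leaf-top / 40 under-leaf / 37 predator individuals
  spread over the historical site/day layout, 26 under-leaf individuals
  with two bracketing sensors (144 sensor streams in all), 10-minute
  sampling, mandatory seed; identical seeds reproduce output bit for bit.

What the generator does *not* emulate: cloud dynamics within a day,
spatial correlation between neighbouring plants, sensor drift over days,
astronomical sun position, or temperature/humidity microclimates. Passing
tests therefore certify the pipeline's arithmetic and the statistical
machinery under the model's assumptions — they do not certify that real
forest-edge light follows a half-cosine.

## 6. Numerical choices and problem sizes

* Counter arithmetic uses doubles; all codes stay far below $2^{53}$, so
  floor/modulo are exact.
* Piecewise-linear interpolation everywhere extrapolates linearly from the
  end segments; the light inversion floors below-grid results at 0 lux.
* Simulation studies in the test suite use: 200 replicates for parameter
  recovery and interval coverage at the full field design (118 × 40);
  500 replicates for the type-I error of the group test, also at the full
  field design; 100 seeds for the generator's midday-mean tuning check.
  Simulation fits use a single optimiser start from the moment-based
  initialiser, which the restart study showed to be reliable on these
  designs.
* The Wald group test is asymptotic in the number of individuals and runs
  slightly liberal in small cluster counts; the containment-DF t tests in
  the contrast table are the finite-sample-safer summary.

## 7. Known limitations

* The sensor model is first-order affine; real harvesters saturate at high
  irradiance and the printed bench nonlinearity (−37% to +14%) is larger
  than the defaults produce. The validation machinery measures whatever
  the parameters generate; the defaults are conservative.
* REML standard errors for $\beta$ treat $(\tau^2, \sigma^2, \phi)$ as
  known; no Kenward–Roger or Satterthwaite correction is attempted
  (deliberately out of scope).
* The piecewise-linear global model cannot represent curvature within a
  grid cell; the off-grid round-trip error (a few percent) is the price,
  and the tests pin it.
* Calibration assumes stability between bench and field; drift,
  re-calibration scheduling and battery discharge curves are out of scope.
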