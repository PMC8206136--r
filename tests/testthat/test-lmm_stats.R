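test_that("log transform maps zero to zero and is monotone", {
  expect_equal(log_lux(0), 0)
  expect_equal(log_lux(999), 3)
  x <- c(0, 1, 10, 500, 7e4)
  expect_true(all(diff(log_lux(x)) > 0))
  expect_error(log_lux(-1), "non-negative")
  # alternative base only rescales
  expect_equal(log_lux(999, base = exp(1)), 3 * log(10))
})

test_that("normality screen rejects skewed lux data and behaves under the null", {
  set.seed(202)
  skewed <- rlnorm(500, 5, 1.5)
  res <- normality_screen(skewed)
  expect_lt(res$p_value, 1e-6)
  expect_lte(res$W, 1)
  # under a true normal, p > 0.05 in at least 90% of repetitions
  hits <- vapply(1:100, function(i) {
    set.seed(i)
    normality_screen(rnorm(50))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # subsampling above the implementation limit is reproducible
  big <- rlnorm(6000, 5, 1)
  expect_identical(normality_screen(big, seed = 2),
                   normality_screen(big, seed = 2))
  expect_true(normality_screen(big)$subsampled)
  expect_error(normality_screen(rep(1, 10)), "constant")
})

test_that("tiny-instance REML matches the dense brute-force oracle", {
  # 2 individuals x 3 timepoints, values fixed in-line
  df <- tibble::tibble(
    individual = rep(c("a", "b"), each = 3),
    time_idx = rep(0:2, 2),
    y = c(1.2, 1.9, 1.6, 2.8, 2.4, 3.1)
  )
  X <- cbind(1, df$time_idx)
  # agreement of the likelihood surfaces at arbitrary admissible points
  for (pars in list(c(0.3, 0.5, 0.2), c(0.01, 1.2, -0.4), c(1.5, 0.2, 0.7))) {
    ours <- -luxdose:::reml_eval(
      luxdose:::build_reml_problem(df$y, X, df$individual, df$time_idx),
      pars[1], pars[2], pars[3])$m2ll / 2
    theirs <- oracle_reml_loglik(df$y, X, df$individual, df$time_idx,
                                 pars[1], pars[2], pars[3])
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
  # the package optimum is not beaten by the oracle optimiser
  fit <- luxdose:::fit_reml_ar1(df$y, X, df$individual, df$time_idx, seed = 4)
  oracle <- oracle_reml_maximise(df$y, X, df$individual, df$time_idx)
  expect_lt(abs(fit$logLik_reml - oracle$loglik), 1e-8)
})

test_that("REML optimum dominates random admissible parameter points", {
  d <- simulate_lmm_study(n_per_group = c(3, 3, 2), n_bins = 6,
                          tau2 = 0.2, sigma2 = 0.4, phi = 0.4, seed = 9)
  fit <- fit_lmm_ar1(d, transform = FALSE, seed = 9)
  set.seed(77)
  cand <- replicate(1000, c(runif(1, 1e-4, 2), runif(1, 1e-3, 2),
                            runif(1, -0.95, 0.95)))
  lls <- apply(cand, 2, function(p) reml_loglik_at(fit, p[1], p[2], p[3]))
  expect_true(all(lls <= fit$logLik_reml + 1e-6))
})

test_that("degenerate covariance reduces to ordinary least squares", {
  # with phi fixed at 0 and balanced data, the GLS fixed effects coincide
  # with OLS regardless of the intercept variance
  d <- simulate_lmm_study(n_per_group = c(6, 6, 6), n_bins = 8,
                          tau2 = 0, sigma2 = 0.3, phi = 0, seed = 12)
  fit0 <- fit_lmm_ar1(d, transform = FALSE, ar1 = FALSE, seed = 1)
  ols <- lm(y ~ category * time_idx, data = d)
  expect_equal(unname(fit0$beta), unname(coef(ols)), tolerance = 1e-6)
  expect_identical(fit0$phi, 0)
})

test_that("estimates agree with an independent mixed-model implementation", {
  d <- simulate_lmm_study(n_per_group = c(8, 7, 6), n_bins = 12,
                          missing_frac = 0.1, seed = 31)
  fit <- fit_lmm_ar1(d, transform = FALSE, seed = 2)
  dd <- as.data.frame(d)
  lf <- nlme::lme(y ~ category * time_idx, random = ~1 | individual,
                  correlation = nlme::corAR1(form = ~time_idx | individual),
                  data = dd, method = "REML", na.action = na.exclude)
  expect_equal(unname(fit$beta), unname(nlme::fixef(lf)), tolerance = 1e-5)
  expect_equal(fit$sigma2, lf$sigma^2, tolerance = 1e-3)
  expect_equal(fit$phi,
               coef(lf$modelStruct$corStruct, unconstrained = FALSE)[[1]],
               tolerance = 1e-3)
  expect_equal(fit$tau2, as.numeric(nlme::VarCorr(lf)[1, 1]),
               tolerance = 1e-3)
  # Wald table against the reference implementation
  ours <- wald_anova(fit)
  theirs <- car::Anova(lf, type = "II")
  expect_equal(ours$chisq, unname(theirs$Chisq), tolerance = 1e-4)
  expect_equal(ours$df, unname(theirs$Df))
  # contrasts against emmeans (containment df, Tukey adjustment)
  em <- summary(emmeans::contrast(
    emmeans::emmeans(lf, ~category,
                     at = list(time_idx = mean(dd$time_idx))),
    method = "pairwise"), adjust = "tukey")
  # emmeans orders pairs (1-2, 1-3, 2-3); ours are (1-2, 2-3, 1-3)
  ours_c <- tukey_contrasts(fit)[c(1, 3, 2), ]
  expect_equal(abs(ours_c$estimate), abs(em$estimate), tolerance = 1e-5)
  expect_equal(ours_c$se, em$SE, tolerance = 1e-5)
  expect_equal(ours_c$df, em$df)
  expect_equal(ours_c$p_value, em$p.value, tolerance = 1e-4)
})

test_that("ANOVA table has fixed factor degrees of freedom", {
  d <- simulate_lmm_study(n_per_group = c(4, 4, 4), n_bins = 6, seed = 8)
  fit <- fit_lmm_ar1(d, transform = FALSE, seed = 8)
  an <- wald_anova(fit)
  expect_equal(an$term, c("category", "time_idx", "category:time_idx"))
  expect_equal(an$df, c(2L, 1L, 2L))
  expect_true(all(an$p_value >= 0 & an$p_value <= 1))
  an3 <- wald_anova(fit, type = "III")
  expect_equal(an3$df, c(2L, 1L, 2L))
})

test_that("rescaling the response leaves the chi-squares invariant", {
  d <- simulate_lmm_study(n_per_group = c(5, 5, 5), n_bins = 8, seed = 19)
  f1 <- fit_lmm_ar1(d, transform = FALSE, seed = 3)
  # multiplying every lux value by a constant adds a constant on the log
  # scale: only the intercept moves
  d2 <- dplyr::mutate(d, y = y + log10(7))
  f2 <- fit_lmm_ar1(d2, transform = FALSE, seed = 3)
  expect_equal(wald_anova(f1)$chisq, wald_anova(f2)$chisq, tolerance = 1e-4)
  expect_equal(unname(f1$beta[-1]), unname(f2$beta[-1]), tolerance = 1e-5)
  expect_equal(unname(f2$beta[1] - f1$beta[1]), log10(7), tolerance = 1e-5)
})

test_that("Tukey contrasts: structure, null behaviour and adjustment", {
  # null simulation: no group differences
  d0 <- simulate_lmm_study(n_per_group = c(10, 10, 10), n_bins = 10,
                           beta = c(3, 0, 0, 0.01, 0, 0), seed = 55)
  fit0 <- fit_lmm_ar1(d0, transform = FALSE, seed = 5)
  ct0 <- tukey_contrasts(fit0)
  expect_equal(nrow(ct0), 3)
  expect_equal(unique(ct0$df), 27)
  expect_true(all(abs(ct0$estimate) < 0.5))
  expect_true(all(ct0$p_value > 0.1))
  # adjusted p never smaller than the unadjusted t-test p
  d1 <- simulate_lmm_study(n_per_group = c(6, 6, 6), n_bins = 8, seed = 66)
  ct1 <- tukey_contrasts(fit_lmm_ar1(d1, transform = FALSE, seed = 6))
  raw_p <- 2 * pt(abs(ct1$t_ratio), df = ct1$df, lower.tail = FALSE)
  expect_true(all(ct1$p_value >= raw_p - 1e-12))
})

test_that("estimated AR(1) correlation tracks the generating value", {
  phis <- c(0, 0.3, 0.6, 0.9)
  est <- vapply(seq_along(phis), function(i) {
    d <- simulate_lmm_study(n_per_group = c(10, 10, 10), n_bins = 15,
                            phi = phis[i], seed = 100 + i)
    fit_lmm_ar1(d, transform = FALSE, n_restarts = 1, seed = i)$phi
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(max(abs(est - phis)), 0.25)
})

test_that("input validation guards the model's preconditions", {
  d <- simulate_lmm_study(n_per_group = c(3, 3, 3), n_bins = 5, seed = 2)
  expect_error(fit_lmm_ar1(d[d$category != "predator", ], transform = FALSE),
               "3 exposure groups")
  d_one <- d[d$individual != "ind_001" | d$time_idx == 0, ]
  expect_error(fit_lmm_ar1(d_one, transform = FALSE), "2 timepoints")
  dup <- dplyr::bind_rows(d, d[1, ])
  expect_error(fit_lmm_ar1(dup, transform = FALSE), "duplicate")
})

test_that("tidy and glance expose the fit in broom style", {
  d <- simulate_lmm_study(n_per_group = c(4, 4, 4), n_bins = 6, seed = 14)
  fit <- fit_lmm_ar1(d, transform = FALSE, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- glance(fit)
  expect_equal(gl$n_individuals, 12)
  expect_true(gl$sigma2 > 0 && gl$tau2 >= 0 && abs(gl$phi) < 1)
})
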