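# Inference stage: log transform, normality screen, repeated-measures linear
# mixed model with random individual intercepts and AR(1) within-individual
# errors (REML), Wald chi-square ANOVA, and Tukey-adjusted pairwise group
# contrasts.
#
# The marginal covariance of individual i observed at bin times t is
#   V_i = tau2 * J + sigma2 * R(phi),  R_jk = phi^|t_j - t_k|,
# so gaps in an individual's series are handled by the power decay. The REML
# criterion is maximised over (log tau2, log sigma2, atanh phi) with the
# fixed effects profiled out by generalised least squares at each candidate.

#' Log transform for illuminance
#'
#' `log(lux + offset)` in the configured base; the unit offset makes zero lux
#' map to zero and keeps the transform defined on the whole measurement
#' range.
#'
#' @param lux Non-negative illuminance values.
#' @param base Logarithm base (default 10).
#' @param offset Additive offset before the log (default 1).
#' @return Transformed values.
#' @export
#' @examples
#' log_lux(c(0, 999))
log_lux <- function(lux, base = 10, offset = 1) {
  if (any(lux < 0, na.rm = TRUE)) {
    stop("`lux` must be non-negative", call. = FALSE)
  }
  log(lux + offset, base = base)
}

#' Shapiro-Wilk normality screen
#'
#' Wraps `shapiro.test`, subsampling (reproducibly) above the test's
#' implementation limit and flagging degenerate input.
#'
#' @param x Numeric sample (n >= 3).
#' @param max_n Largest sample passed to the test; larger samples are
#'   subsampled to this size.
#' @param seed Seed for the subsample.
#' @return Tibble with `W`, `p_value`, `n_used`, `subsampled`.
#' @export
normality_screen <- function(x, max_n = 5000, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("need at least 3 finite values", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("constant input: normality test undefined", call. = FALSE)
  }
  subsampled <- length(x) > max_n
  if (subsampled) {
    local_seed(seed)
    x <- sample(x, max_n)
  }
  st <- stats::shapiro.test(x)
  tibble::tibble(
    W = unname(st$statistic), p_value = st$p.value,
    n_used = length(x), subsampled = subsampled
  )
}

# ---- REML machinery -------------------------------------------------------

# Pre-digest clusters: split rows by individual, then pool individuals that
# share both a time grid and a fixed-effect design block (for balanced data,
# one pool per group). Each pool stores its design block once and the
# responses as a column-per-individual matrix, so one Cholesky and one
# triangular solve per pool serve all its individuals at every evaluation.
build_reml_problem <- function(y, X, id, time) {
  stopifnot(length(y) == nrow(X), length(id) == length(y),
            length(time) == length(y))
  ord <- order(id, time)
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  id <- id[ord]; time <- time[ord]
  idx <- split(seq_along(y), id)
  keys <- vapply(idx, function(ii) {
    ti <- time[ii]
    if (anyDuplicated(ti)) {
      stop("duplicate time points within an individual", call. = FALSE)
    }
    paste(c(ti, signif(X[ii, ], 12)), collapse = ",")
  }, "")
  pools <- lapply(split(idx, keys), function(group_idx) {
    ii1 <- group_idx[[1]]
    list(
      X = X[ii1, , drop = FALSE],
      t = time[ii1],
      Y = matrix(vapply(group_idx, function(ii) y[ii],
                        numeric(length(ii1))), nrow = length(ii1)),
      m = length(group_idx)
    )
  })
  list(pools = pools, n = length(y), p = ncol(X),
       n_clusters = length(idx))
}

# Minus twice the REML log-likelihood at (tau2, sigma2, phi), with the GLS
# beta and its covariance as by-products.
reml_eval <- function(prob, tau2, sigma2, phi) {
  p <- prob$p
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  yVy <- 0
  logdet <- 0
  for (pool in prob$pools) {
    R <- phi^abs(outer(pool$t, pool$t, "-"))
    V <- tau2 + sigma2 * R
    L <- t(chol(V))
    Zx <- forwardsolve(L, pool$X)
    Zy <- forwardsolve(L, pool$Y)
    if (is.null(dim(Zy))) Zy <- matrix(Zy, ncol = pool$m)
    XtVX <- XtVX + pool$m * crossprod(Zx)
    XtVy <- XtVy + drop(crossprod(Zx, rowSums(Zy)))
    yVy <- yVy + sum(Zy^2)
    logdet <- logdet + pool$m * 2 * sum(log(diag(L)))
  }
  chol_XtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chol_XtVX)) return(list(m2ll = Inf))
  beta <- backsolve(chol_XtVX, forwardsolve(t(chol_XtVX), XtVy))
  yPy <- yVy - sum(XtVy * beta)
  logdet_XtVX <- 2 * sum(log(diag(chol_XtVX)))
  m2ll <- logdet + logdet_XtVX + yPy + (prob$n - p) * log(2 * pi)
  vcov_beta <- chol2inv(chol_XtVX)
  list(m2ll = m2ll, beta = drop(beta), vcov = vcov_beta, yPy = yPy)
}

#' REML log-likelihood of the AR(1) random-intercept model at given
#' variance parameters
#'
#' Evaluates the restricted log-likelihood of a fitted model's data at
#' arbitrary admissible `(tau2, sigma2, phi)`, with the fixed effects
#' profiled out. Used for profile exploration and for verifying that the
#' optimiser's solution dominates alternatives.
#'
#' @param fit A [fit_lmm_ar1()] object.
#' @param tau2 Random-intercept variance (>= 0).
#' @param sigma2 Residual innovation variance (> 0).
#' @param phi AR(1) correlation in (-1, 1).
#' @return The REML log-likelihood (scalar).
#' @export
reml_loglik_at <- function(fit, tau2, sigma2, phi) {
  stopifnot(tau2 >= 0, sigma2 > 0, abs(phi) < 1)
  -reml_eval(fit$problem, tau2, sigma2, phi)$m2ll / 2
}

fit_reml_ar1 <- function(y, X, id, time, n_restarts = 3, seed = 1L,
                         phi_max = 0.995, ar1 = TRUE) {
  prob <- build_reml_problem(y, X, id, time)
  # moment-style start: between-individual spread of means vs within spread
  cl_means <- unlist(lapply(prob$pools, function(pool) colMeans(pool$Y)))
  v_tot <- stats::var(y)
  tau2_0 <- max(stats::var(cl_means) * 0.5, v_tot * 0.05, 1e-4)
  sigma2_0 <- max(v_tot - tau2_0, v_tot * 0.1, 1e-4)
  theta0 <- c(log(tau2_0), log(sigma2_0), if (ar1) atanh(0.3))

  objective <- function(theta) {
    phi <- if (ar1) tanh(theta[3]) else 0
    reml_eval(prob, exp(theta[1]), exp(theta[2]), phi)$m2ll
  }
  lower <- c(log(1e-10), log(1e-10), if (ar1) atanh(-phi_max))
  upper <- c(log(1e6), log(1e6), if (ar1) atanh(phi_max))

  local_seed(seed)
  starts <- list(theta0)
  if (n_restarts > 1) {
    for (k in seq_len(n_restarts - 1)) {
      starts[[k + 1]] <- theta0 + stats::rnorm(length(theta0), 0, 0.7)
    }
  }
  best <- NULL
  any_converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      stats::nlminb(s, objective, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("REML optimisation failed on all starts",
                          call. = FALSE)
  if (!any_converged) {
    stop(sprintf(
      paste0("REML optimisation did not converge; best -2*logLik so far ",
             "%.6f at tau2=%.4g sigma2=%.4g phi=%.4f"),
      best$objective, exp(best$par[1]), exp(best$par[2]),
      if (ar1) tanh(best$par[3]) else 0
    ), call. = FALSE)
  }
  tau2 <- exp(best$par[1]); sigma2 <- exp(best$par[2])
  phi <- if (ar1) tanh(best$par[3]) else 0
  if (ar1 && abs(phi) > 0.99 * phi_max) {
    warning("AR(1) parameter estimated at its boundary (phi = ",
            signif(phi, 4), ")")
  }
  at_opt <- reml_eval(prob, tau2, sigma2, phi)
  list(problem = prob, beta = at_opt$beta, vcov = at_opt$vcov,
       tau2 = tau2, sigma2 = sigma2, phi = phi,
       logLik_reml = -at_opt$m2ll / 2,
       n_obs = prob$n, n_individuals = prob$n_clusters)
}

#' Fit the repeated-measures AR(1) mixed model
#'
#' Fits `response ~ group + time + group:time` with a random intercept per
#' individual and AR(1) correlation over bin time within individual, by
#' REML. `group` is the three-level exposure category and `time` the
#' continuous 0-based bin index; missing bins are simply absent (excluded)
#' and enter the correlation through the time gap.
#'
#' @param data Analysis table with columns `individual`, `category`,
#'   `time_idx`, and `lux` (or a pre-transformed response `y` when
#'   `transform = FALSE`).
#' @param transform Apply [log_lux()] to `lux` (default) or use `data$y`
#'   as-is.
#' @param log_base,offset Passed to [log_lux()].
#' @param n_restarts Optimiser restarts (jittered starts, fixed seed).
#' @param seed Seed for restart jitter.
#' @param ar1 Estimate the AR(1) correlation (default)? `FALSE` fixes
#'   `phi = 0`, giving the random-intercept-only model.
#' @return An object of class `lux_lmm`: fixed effects and covariance,
#'   variance components (`tau2`, `sigma2`, `phi`), REML log-likelihood and
#'   bookkeeping used by [wald_anova()] and [tukey_contrasts()].
#' @export
fit_lmm_ar1 <- function(data, transform = TRUE, log_base = 10, offset = 1,
                        n_restarts = 3, seed = 1L, ar1 = TRUE) {
  stopifnot(all(c("individual", "category", "time_idx") %in% names(data)))
  data <- data[stats::complete.cases(
    data[, c("individual", "category", "time_idx",
             if (transform) "lux" else "y")]), ]
  data$category <- droplevels(factor(data$category))
  if (nlevels(data$category) != 3) {
    stop("exactly 3 exposure groups are required", call. = FALSE)
  }
  per_group <- table(unique(data[, c("individual", "category")])$category)
  if (any(per_group < 2)) {
    stop("need at least 2 individuals per group", call. = FALSE)
  }
  per_ind <- table(data$individual)
  if (any(per_ind < 2)) {
    stop("need at least 2 timepoints per individual", call. = FALSE)
  }
  y <- if (transform) log_lux(data$lux, base = log_base, offset = offset)
       else data$y
  mf <- stats::model.frame(~ category * time_idx, data = data)
  X <- stats::model.matrix(~ category * time_idx, mf)
  fit <- fit_reml_ar1(y, X, data$individual, data$time_idx,
                      n_restarts = n_restarts, seed = seed, ar1 = ar1)
  names(fit$beta) <- colnames(X)
  dimnames(fit$vcov) <- list(colnames(X), colnames(X))
  structure(
    c(fit, list(
      assign = attr(X, "assign"),
      term_labels = attr(stats::terms(mf), "term.labels"),
      groups = levels(data$category),
      time_mean = mean(data$time_idx),
      transform = if (transform) list(base = log_base, offset = offset)
                  else NULL,
      data = tibble::as_tibble(data)
    )),
    class = "lux_lmm"
  )
}

#' @export
print.lux_lmm <- function(x, ...) {
  cat("<lux_lmm> REML random-intercept + AR(1) model\n")
  cat(sprintf("  %d observations, %d individuals, groups: %s\n",
              x$n_obs, x$n_individuals, paste(x$groups, collapse = ", ")))
  cat(sprintf("  tau2 = %.4g, sigma2 = %.4g, phi = %.4f, REML logLik = %.3f\n",
              x$tau2, x$sigma2, x$phi, x$logLik_reml))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Broom-style tidier for `lux_lmm` fits
#'
#' @param x A [fit_lmm_ar1()] object.
#' @param ... Unused.
#' @return One row per fixed effect: estimate, standard error, z statistic
#'   and Wald p-value.
#' @method tidy lux_lmm
#' @export
tidy.lux_lmm <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(x$beta / se),
    p.value = 2 * stats::pnorm(abs(x$beta / se), lower.tail = FALSE)
  )
}

#' @describeIn tidy.lux_lmm One-row model summary (variance components,
#'   AR(1) parameter, REML log-likelihood, sizes).
#' @method glance lux_lmm
#' @export
glance.lux_lmm <- function(x, ...) {
  tibble::tibble(
    tau2 = x$tau2, sigma2 = x$sigma2, phi = x$phi,
    logLik = x$logLik_reml, nobs = x$n_obs, n_individuals = x$n_individuals
  )
}

# Wald chi-square for the joint nullity of a coefficient subset.
wald_stat <- function(beta, vcov, cols) {
  if (length(cols) == 0) return(0)
  b <- beta[cols]
  drop(t(b) %*% solve(vcov[cols, cols, drop = FALSE], b))
}

#' Wald chi-square ANOVA table
#'
#' Factor-level tests built from the fixed-effect estimates and their
#' covariance. Type II (the default) respects marginality: each term is
#' tested after every other term except those containing it, via the
#' difference of nested Wald statistics; Type III tests each term's
#' coefficients directly. For the three-group model the degrees of freedom
#' are 2 (Group), 1 (Time), 2 (Group x Time).
#'
#' @param fit A [fit_lmm_ar1()] object.
#' @param type `"II"` (default) or `"III"`.
#' @return Tibble: `term`, `chisq`, `df`, `p_value`.
#' @export
wald_anova <- function(fit, type = c("II", "III")) {
  type <- match.arg(type)
  if (any(!is.finite(fit$vcov))) stop("singular fixed-effect covariance",
                                      call. = FALSE)
  labels <- fit$term_labels
  factors <- lapply(strsplit(labels, ":", fixed = TRUE), sort)
  rows <- purrr::map_dfr(seq_along(labels), function(j) {
    cols_j <- which(fit$assign == j)
    if (type == "III") {
      chisq <- wald_stat(fit$beta, fit$vcov, cols_j)
    } else {
      contains_j <- which(vapply(
        seq_along(labels),
        function(k) k != j && all(factors[[j]] %in% factors[[k]]),
        logical(1)
      ))
      rel_cols <- which(fit$assign %in% contains_j)
      chisq <- wald_stat(fit$beta, fit$vcov, c(rel_cols, cols_j)) -
        wald_stat(fit$beta, fit$vcov, rel_cols)
    }
    tibble::tibble(term = labels[j], chisq = chisq, df = length(cols_j))
  })
  dplyr::mutate(rows,
                p_value = stats::pchisq(.data$chisq, .data$df,
                                        lower.tail = FALSE))
}

#' Tukey-adjusted pairwise group contrasts
#'
#' Pairwise differences of the group marginal means evaluated at the mean of
#' the time covariate, with standard errors from the fixed-effect
#' covariance, containment degrees of freedom `n_individuals - n_groups`,
#' and familywise adjustment via the studentized-range distribution with
#' three means.
#'
#' @param fit A [fit_lmm_ar1()] object.
#' @param at_time Time covariate value at which marginal means are compared;
#'   defaults to the observed mean.
#' @return Tibble with 3 rows: `contrast`, `estimate`, `se`, `df`,
#'   `t_ratio`, `p_value`.
#' @export
tukey_contrasts <- function(fit, at_time = NULL) {
  g <- fit$groups
  if (length(g) != 3) stop("contrasts require exactly 3 groups",
                           call. = FALSE)
  tbar <- at_time %||% fit$time_mean
  p <- length(fit$beta)
  # marginal-mean rows in coefficient space (treatment coding)
  mm <- matrix(0, 3, p, dimnames = list(g, names(fit$beta)))
  mm[, "(Intercept)"] <- 1
  mm[, "time_idx"] <- tbar
  for (k in 2:3) {
    mm[k, paste0("category", g[k])] <- 1
    mm[k, paste0("category", g[k], ":time_idx")] <- tbar
  }
  pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  L <- t(vapply(pairs, function(pr) mm[pr[1], ] - mm[pr[2], ], numeric(p)))
  est <- drop(L %*% fit$beta)
  se <- sqrt(diag(L %*% fit$vcov %*% t(L)))
  df <- fit$n_individuals - 3
  t_ratio <- est / se
  tibble::tibble(
    contrast = vapply(pairs, function(pr) paste(g[pr[1]], "vs", g[pr[2]]), ""),
    estimate = est, se = se, df = df, t_ratio = t_ratio,
    p_value = stats::ptukey(sqrt(2) * abs(t_ratio), nmeans = 3, df = df,
                            lower.tail = FALSE)
  )
}

#' Simulate data from the repeated-measures model
#'
#' Draws a dataset with the study's structure directly from the mixed model:
#' per-individual random intercepts, stationary AR(1) residuals, and the
#' fixed-effect structure `group + time + group:time` on the log scale. Used
#' for parameter-recovery, coverage and type-I-error studies.
#'
#' @param n_per_group Individuals per group (default the field design
#'   41/40/37).
#' @param n_bins Number of 10-min bins (default 40).
#' @param beta Fixed effects in treatment coding, in the order (Intercept),
#'   group2, group3, time, group2:time, group3:time.
#' @param tau2,sigma2,phi Variance components and AR(1) correlation.
#' @param missing_frac Fraction of rows dropped completely at random.
#' @param seed Seed.
#' @param log_base,offset Transform parameters used to also emit a `lux`
#'   column (`base^y - offset`, floored at 0).
#' @return Tibble (`individual`, `category`, `time_idx`, `y`, `lux`).
#' @export
simulate_lmm_study <- function(n_per_group = c(41, 40, 37), n_bins = 40,
                               beta = c(3.5, -0.4, -1.2, 0.02, -0.01, -0.02),
                               tau2 = 0.25, sigma2 = 0.36, phi = 0.6,
                               missing_frac = 0, seed = 1L,
                               log_base = 10, offset = 1) {
  stopifnot(length(n_per_group) == 3, length(beta) == 6,
            tau2 >= 0, sigma2 > 0, abs(phi) < 1)
  local_seed(seed)
  groups <- factor(rep(FIELD_CATEGORIES, n_per_group),
                   levels = FIELD_CATEGORIES)
  n_ind <- sum(n_per_group)
  tt <- 0:(n_bins - 1)
  out <- purrr::map_dfr(seq_len(n_ind), function(i) {
    g <- as.integer(groups[i])
    mu <- beta[1] + c(0, beta[2], beta[3])[g] +
      (beta[4] + c(0, beta[5], beta[6])[g]) * tt
    b_i <- stats::rnorm(1, 0, sqrt(tau2))
    e <- numeric(n_bins)
    e[1] <- stats::rnorm(1, 0, sqrt(sigma2))
    if (n_bins > 1) {
      innov <- stats::rnorm(n_bins - 1, 0, sqrt(sigma2 * (1 - phi^2)))
      for (t in 2:n_bins) e[t] <- phi * e[t - 1] + innov[t - 1]
    }
    tibble::tibble(
      individual = sprintf("ind_%03d", i),
      category = groups[i],
      time_idx = tt,
      y = mu + b_i + e
    )
  })
  if (missing_frac > 0) {
    keep <- stats::runif(nrow(out)) >= missing_frac
    out <- out[keep, ]
  }
  out$lux <- pmax(log_base^out$y - offset, 0)
  out
}
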