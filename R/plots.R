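# Figure-style views of the pipeline outputs.

category_palette <- c(leaf_top = "#E69F00", under_leaf = "#0072B2",
                      predator = "#D55E00")

#' Mean +/- SE daily exposure profiles by category
#'
#' @param summary A [summarize_light()] table.
#' @return A ggplot.
#' @export
plot_daily_profiles <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = as.numeric(.data$time_bin) / 3600,
                               y = .data$mean, colour = .data$category,
                               fill = .data$category)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = category_palette) +
    ggplot2::scale_fill_manual(values = category_palette) +
    ggplot2::labs(x = "local time (h)", y = "illuminance (lux)",
                  colour = "category", fill = "category",
                  title = "Mean daily solar exposure ± SE") +
    ggplot2::theme_minimal()
}

#' Median / quartile daily profiles by category
#'
#' Boxplot-style view: median line, interquartile band, and 1.5 x IQR
#' whisker band per category over the analysis window.
#'
#' @param summary A [summarize_light()] table.
#' @return A ggplot.
#' @export
plot_daily_boxes <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = as.numeric(.data$time_bin) / 3600,
                               colour = .data$category,
                               fill = .data$category)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$whisker_lo, 0),
                                      ymax = .data$whisker_hi),
                         alpha = 0.12, colour = NA) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.3, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = category_palette) +
    ggplot2::scale_fill_manual(values = category_palette) +
    ggplot2::labs(x = "local time (h)", y = "illuminance (lux)",
                  colour = "category", fill = "category",
                  title = "Daily exposure: median, IQR, 1.5×IQR") +
    ggplot2::theme_minimal()
}

#' Per-individual exposure scatter for one category
#'
#' @param tidy A [build_tidy_table()] result.
#' @param category Category to display.
#' @return A ggplot.
#' @export
plot_individual_series <- function(tidy, category = "leaf_top") {
  dat <- tidy[tidy$category == category, ]
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = as.numeric(.data$time_bin) / 3600,
                               y = .data$lux)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7,
                        colour = category_palette[[category]]) +
    ggplot2::labs(x = "local time (h)", y = "illuminance (lux)",
                  title = paste("Individual readings:", category)) +
    ggplot2::theme_minimal()
}

#' Model view: group marginal means at mean time with 95% intervals
#'
#' @param object A [fit_lmm_ar1()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lux_lmm
#' @export
autoplot.lux_lmm <- function(object, ...) {
  tbar <- object$time_mean
  g <- object$groups
  p <- length(object$beta)
  mm <- matrix(0, 3, p, dimnames = list(g, names(object$beta)))
  mm[, "(Intercept)"] <- 1
  mm[, "time_idx"] <- tbar
  for (k in 2:3) {
    mm[k, paste0("category", g[k])] <- 1
    mm[k, paste0("category", g[k], ":time_idx")] <- tbar
  }
  est <- drop(mm %*% object$beta)
  se <- sqrt(diag(mm %*% object$vcov %*% t(mm)))
  dat <- tibble::tibble(category = factor(g, levels = g), mean = est,
                        lo = est - 1.96 * se, hi = est + 1.96 * se)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$mean,
                                    colour = .data$category)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::scale_colour_manual(values = category_palette, guide = "none") +
    ggplot2::labs(x = NULL, y = "marginal mean (log scale)",
                  title = "Group marginal means at mean time, 95% CI") +
    ggplot2::theme_minimal()
}
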