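#' Plot standardized survival curves
#'
#' Step curves of standardized survival per strategy, with percentile
#' confidence ribbons when bootstrap CIs are attached.
#'
#' @param object A `ccw_survival_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ccw_survival_result <- function(object, ...) {
  d <- object$curves
  has_ci <- "risk_ci_lower" %in% names(d)
  d0 <- d[d$interval == 1, ]
  d0$interval <- 0
  d0$risk <- 0
  d0$survival <- 1
  if (has_ci) {
    d0$risk_ci_lower <- 0
    d0$risk_ci_upper <- 0
  }
  d <- dplyr::bind_rows(d0, d)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$interval, y = .data$survival,
                                       colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "follow-up interval", y = "standardized survival",
                  colour = "strategy") +
    ggplot2::theme_minimal()
  if (has_ci) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 1 - .data$risk_ci_upper,
                   ymax = 1 - .data$risk_ci_lower, fill = .data$arm),
      alpha = 0.15, colour = NA)
  }
  p
}

#' Plot the bootstrap resample distribution
#'
#' @param object A `ccw_boot`.
#' @param ... Unused.
#' @return A ggplot histogram of resampled hazard ratios.
#' @export
autoplot.ccw_boot <- function(object, ...) {
  d <- object$resamples[!is.na(object$resamples$hr), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$hr$hazard_ratio, colour = "red") +
    ggplot2::labs(x = "hazard ratio (bootstrap resamples)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot inverse-probability-weight diagnostics
#'
#' Per-interval mean cumulative weight by arm; a correctly specified
#' stabilized weight model keeps the means near 1.
#'
#' @param diagnostics Output of [weight_diagnostics()].
#' @param tolerance Reference band half-width around 1.
#' @return A ggplot object.
#' @export
plot_weight_diagnostics <- function(diagnostics, tolerance = 0.05) {
  ggplot2::ggplot(diagnostics,
                  ggplot2::aes(x = .data$interval, y = .data$mean,
                               colour = .data$arm)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_hline(yintercept = c(1 - tolerance, 1 + tolerance),
                        linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "follow-up interval", y = "mean cumulative weight",
                  colour = "arm") +
    ggplot2::theme_minimal()
}
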