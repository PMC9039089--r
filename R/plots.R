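#' Plot single-cell fluorescence trajectories
#'
#' Spaghetti plot of per-cell intensity over time, coloured by
#' subpopulation when present.
#'
#' @param cells Trajectory tibble.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(cells, alpha = 0.4) {
  aes <- if ("subpopulation" %in% names(cells) &&
             !all(is.na(cells$subpopulation))) {
    ggplot2::aes(x = .data$t_h, y = .data$intensity, group = .data$cell_id,
                 colour = .data$subpopulation)
  } else {
    ggplot2::aes(x = .data$t_h, y = .data$intensity, group = .data$cell_id)
  }
  ggplot2::ggplot(cells, aes) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "time (h)", y = "fluorescence (a.u.)")
}

#' Plot continuized Hilbert phases
#'
#' @param phases Tidy phase tibble with `cell_id`, `t_h`, `F_C` columns.
#' @return A ggplot object.
#' @export
plot_phases <- function(phases) {
  ggplot2::ggplot(phases, ggplot2::aes(x = .data$t_h, y = .data$F_C,
                                       group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (h)", y = "continuized Hilbert phase (rad)")
}

#' Plot a periodogram
#'
#' @param p A [periodogram()] tibble.
#' @param max_period_h Clip the period axis (default 60 h).
#' @return A ggplot object.
#' @export
plot_periodogram <- function(p, max_period_h = 60) {
  ggplot2::ggplot(dplyr::filter(p, .data$period_h <= max_period_h),
                  ggplot2::aes(x = .data$period_h, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(p, "peak_period_h"),
                        linetype = "dashed") +
    ggplot2::labs(x = "period (h)", y = "power")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Chi-squared trace of an ensemble fit
#'
#' @param object An `ensemble_fit`.
#' @param ... Unused.
#' @return A ggplot object of the chi-squared statistic per sweep.
#' @export
autoplot.ensemble_fit <- function(object, ...) {
  tr <- tibble::tibble(sweep = seq_along(object$chi2_trace),
                       chi2 = object$chi2_trace)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$sweep, y = .data$chi2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sweep", y = expression(chi^2))
}

#' Density-dependence of synchronization
#'
#' Scatter of Kuramoto K against wells per chamber with the robust
#' regression line.
#'
#' @param density,K Density and synchronization values.
#' @return A ggplot object.
#' @export
plot_density_K <- function(density, K) {
  reg <- density_regression(density, K)
  ggplot2::ggplot(tibble::tibble(density = density, K = K),
                  ggplot2::aes(x = .data$density, y = .data$K)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = reg$intercept, slope = reg$slope) +
    ggplot2::labs(x = "wells per chamber", y = "Kuramoto K")
}
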