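#' Developmental-curve plot for one parameter
#'
#' Mean treatment ratio (+/- SEM) over DIV per concentration, faceted by
#' sex, with the benchmark-response band as a grey ribbon — the standard
#' presentation of chronic MEA dose-response data.
#'
#' @param ratios An outlier-excluded [cumulative_ratios()] table.
#' @param parameter One of [metric_names()].
#' @param band Optional [bmr_band()] table; computed from `ratios` when
#'   `NULL`.
#' @return A ggplot object.
#' @export
plot_development <- function(ratios, parameter, band = NULL) {
  stopifnot(inherits(ratios, "mea_ratios"),
            parameter %in% unique(ratios$parameter))
  if (is.null(band)) band <- bmr_band(ratios)
  d <- dplyr::filter(ratios, .data$parameter == !!parameter, !.data$outlier,
                     !is.na(.data$ratio_pct))
  sm <- dplyr::summarise(
    d, mean = mean(.data$ratio_pct),
    sem = sd(.data$ratio_pct) / sqrt(dplyr::n()),
    .by = c("compound", "concentration_uM", "sex", "div"))
  sm$label <- ifelse(sm$concentration_uM == 0, "control",
                     paste0(sm$compound, " ", sm$concentration_uM,
                            " µM"))
  b <- dplyr::filter(band, .data$parameter == !!parameter)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$div, y = .data$mean,
                                   colour = .data$label)) +
    ggplot2::geom_ribbon(
      data = b,
      ggplot2::aes(x = .data$div, ymin = .data$lower_pct,
                   ymax = .data$upper_pct),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.3) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Days in vitro", y = "Treatment ratio (% of control)",
                  colour = NULL, title = parameter) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mea_ratios <- function(object, parameter = "n_network_bursts",
                                ...) {
  plot_development(object, parameter, ...)
}

#' Raster plot of a well-recording
#'
#' Spike raster (electrode vs time) of one simulated or recorded well, the
#' basic diagnostic view of network-burst structure.
#'
#' @param spikes Spike table with `electrode` and `time_s` (one well).
#' @param xlim Optional length-2 time range in seconds.
#' @return A ggplot object.
#' @export
plot_raster <- function(spikes, xlim = NULL) {
  p <- ggplot2::ggplot(spikes, ggplot2::aes(x = .data$time_s,
                                            y = factor(.data$electrode))) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "Time (s)", y = "Electrode") +
    ggplot2::theme_minimal()
  if (!is.null(xlim)) p <- p + ggplot2::coord_cartesian(xlim = xlim)
  p
}
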