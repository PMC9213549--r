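#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a downscaled precipitation-isotope ensemble
#'
#' Ensemble mean with a +/- 1 ensemble-sd ribbon on wet days, with the
#' observed biweekly composites overlaid at their window midpoints.
#'
#' @param object A `"precip_ensemble"`.
#' @param tracer `"d18O"` (default) or `"d2H"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.precip_ensemble <- function(object, tracer = c("d18O", "d2H"), ...) {
  tracer <- match.arg(tracer)
  s <- dplyr::filter(tidy(object), .data$tracer == !!tracer,
                     .data$flag == 0L)
  comp <- dplyr::mutate(
    object$composites,
    date = .data$window_start +
      as.numeric(.data$window_end - .data$window_start) / 2,
    value = .data[[tracer]]
  )
  ggplot2::ggplot(s, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean),
                        colour = "steelblue", size = 0.6) +
    ggplot2::geom_point(data = comp, ggplot2::aes(y = .data$value),
                        colour = "black", shape = 21, fill = "white") +
    ggplot2::labs(
      x = NULL,
      y = paste0(tracer, " (permil)"),
      title = paste("Downscaled daily", tracer, "at", object$site),
      subtitle = "ribbon: ensemble mean +/- 1 sd on wet days; open points: observed biweekly composites"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a daily flux-isotope series
#'
#' Slope estimates with +/- 1 standard-error bars, coloured by quality
#' flag, one panel per time-window.
#'
#' @param object A `"flux_iso"` tibble from [estimate_flux_iso()] (or a
#'   `"flux_series"` from [daily_flux_series()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_iso <- function(object, ...) {
  d <- dplyr::filter(object, .data$flag != 1L)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, y = .data$slope,
                                  colour = factor(.data$flag))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$slope - .data$slope_se,
                                          ymax = .data$slope + .data$slope_se),
                             size = 0.2) +
    ggplot2::facet_grid(
      rows = if ("tracer" %in% names(d)) ggplot2::vars(.data$tracer) else NULL,
      cols = ggplot2::vars(.data$window), scales = "free_y"
    ) +
    ggplot2::labs(x = NULL, y = "flux isotope ratio (permil)",
                  colour = "flag",
                  title = "Daily Miller-Tans flux isotope estimates") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flux_series <- function(object, ...) autoplot.flux_iso(object, ...)
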