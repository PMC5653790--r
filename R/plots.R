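#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial band profile
#'
#' Intensity against radial position (or hours, when a `time_h` column or
#' calibration is available), optionally with detected rings marked.
#'
#' @param object A `radial_profile`.
#' @param rings Optional `ring_set` from [detect_rings()] to overlay.
#' @param calibration Optional [calibrate()] result to draw a time axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radial_profile <- function(object, rings = NULL, calibration = NULL,
                                    ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(calibration) && is.null(df[["time_h"]])) {
    df$time_h <- calibration$pos_to_time(df$position_px)
  }
  use_time <- !is.null(df[["time_h"]])
  xvar <- if (use_time) "time_h" else "position_px"
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xvar]], .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = if (use_time) "time (h)" else "radial position (px)",
                  y = "grayscale intensity") +
    ggplot2::theme_minimal()
  if (!is.null(rings) && nrow(rings)) {
    xr <- if (use_time) {
      rings[["time_h"]] %||% calibration$pos_to_time(rings$position_px)
    } else rings$position_px
    p <- p + ggplot2::geom_vline(xintercept = xr, colour = "firebrick",
                                 linetype = "dashed", alpha = 0.6)
  }
  p
}

#' Plot a periodogram
#'
#' Power against period (h) inside a display band, with the in-band peak
#' marked.
#'
#' @param object A `periodogram`.
#' @param band Display band in hours. Default `c(12, 48)`.
#' @param estimate Optional `period_estimate` whose period is marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.periodogram <- function(object, band = c(12, 48), estimate = NULL,
                                 ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$freq_per_h > 0,
                  1 / .data$freq_per_h >= band[1],
                  1 / .data$freq_per_h <= band[2]) |>
    dplyr::mutate(period_h = 1 / .data$freq_per_h)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$period_h, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "period (h)", y = "power") +
    ggplot2::theme_minimal()
  if (!is.null(estimate)) {
    p <- p + ggplot2::geom_vline(xintercept = estimate$period,
                                 colour = "firebrick", linetype = "dashed") +
      ggplot2::annotate("text", x = estimate$period, y = max(df$power),
                        label = sprintf("%.1f h", estimate$period),
                        hjust = -0.1, vjust = 1, colour = "firebrick")
  }
  p
}

#' Plot a double-plotted actogram
#'
#' Rows stacked top to bottom (day 1 on top), intensity as a grayscale
#' raster, light onsets/offsets marked with triangles when the schedule was
#' supplied to [build_actogram()].
#'
#' @param object An `actogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.actogram <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$hour, .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(object$rows))) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "grey85") +
    ggplot2::labs(x = sprintf("time in row (h, %g h per row)",
                              object$row_hours),
                  y = "day", fill = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(object$light_marks) && nrow(object$light_marks)) {
    m <- object$light_marks
    p <- p +
      ggplot2::geom_point(data = m,
                          ggplot2::aes(x = .data$onset, y = .data$row - 0.45),
                          inherit.aes = FALSE, shape = 2, size = 1.5) +
      ggplot2::geom_point(data = m,
                          ggplot2::aes(x = .data$offset, y = .data$row - 0.45),
                          inherit.aes = FALSE, shape = 17, size = 1.5)
  }
  p
}

#' Plot a temperature-compensation summary
#'
#' Group mean free-running period with SEM error bars per temperature.
#'
#' @param object A `compensation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.compensation_result <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(factor(.data$temperature_C), .data$mean_h)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_h - .data$sem_h,
                                        ymax = .data$mean_h + .data$sem_h),
                           width = 0.15) +
    ggplot2::labs(x = "temperature (°C)",
                  y = "free-running period (h)",
                  subtitle = sprintf("Q10(%g–%g °C) = %.1f",
                                     object$reference_pair[1],
                                     object$reference_pair[2],
                                     object$q10_display)) +
    ggplot2::theme_minimal()
}

#' Save an actogram rendering as PNG
#'
#' @param acto An `actogram`.
#' @param path Output PNG path.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
save_actogram_png <- function(acto, path, width = 6, height = 4, dpi = 150) {
  ggplot2::ggsave(path, autoplot(acto), width = width, height = height,
                  dpi = dpi)
  invisible(path)
}
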