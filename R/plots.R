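# ggplot2 graphics for chromatograms, calibration fits and isotopologue
# distributions.

#' Plot chromatogram traces
#'
#' One panel per channel, overlaying injections. Expected analyte retention
#' times can be marked from a panel.
#'
#' @param chroms Long chromatogram tibble.
#' @param channels Channels to show (default: all present).
#' @param panel Optional `panel_config`; adds dashed retention-time markers.
#' @param xlim Optional time range (min).
#'
#' @return A ggplot object.
#' @export
plot_chromatograms <- function(chroms, channels = unique(chroms$channel),
                               panel = NULL, xlim = NULL) {
  d <- dplyr::filter(chroms, .data$channel %in% channels)
  if (!is.null(xlim)) {
    d <- dplyr::filter(d, .data$time_min >= xlim[1], .data$time_min <= xlim[2])
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(
    .data$time_min, .data$intensity,
    colour = .data$injection_id
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(
      x = "retention time (min)", y = "intensity (counts)",
      colour = "injection"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(panel)) {
    marks <- panel$transitions |>
      dplyr::filter(.data$channel %in% channels) |>
      dplyr::distinct(.data$channel, .data$analyte, .data$rt)
    if (!is.null(xlim)) {
      marks <- dplyr::filter(marks, .data$rt >= xlim[1], .data$rt <= xlim[2])
    }
    p <- p + ggplot2::geom_vline(
      data = marks, ggplot2::aes(xintercept = .data$rt),
      linetype = "dashed", colour = "grey40", linewidth = 0.3
    )
  }
  p
}

#' @export
autoplot.calibration_model <- function(object, ...) {
  d <- object$residuals
  ggplot2::ggplot(d, ggplot2::aes(.data$level, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      colour = "steelblue"
    ) +
    ggplot2::labs(
      title = paste("Calibration:", object$analyte),
      x = "concentration (ng/mL)", y = "response factor"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.isotopologue_distribution <- function(object, ...) {
  d <- tidy.isotopologue_distribution(object)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$shift), .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      title = paste("Isotopologue distribution:", unique(d$formula)),
      x = "nominal mass shift (Da)", y = "probability"
    ) +
    ggplot2::theme_minimal()
}
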