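#' Per-slide density curves with Otsu threshold ticks
#'
#' The visual diagnostic for slide alignment: one density curve per slide
#' for a channel, with each slide's Otsu threshold marked as a tick on the
#' x-axis. Well-normalized data shows overlapping curves and tightly
#' clustered ticks.
#'
#' @param x A `cell_tbl`.
#' @param channel Channel name.
#' @param nbins Histogram bins for the per-slide Otsu thresholds.
#' @return A ggplot object.
#' @export
plot_slide_densities <- function(x, channel, nbins = 256) {
  df <- tibble(slide_id = x$slide_id, value = x[[channel]])
  ticks <- df |>
    group_by(.data$slide_id) |>
    summarise(threshold = tryCatch(otsu_threshold(.data$value, nbins),
                                   error = function(e) NA_real_),
              .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$slide_id)) +
    ggplot2::geom_density() +
    ggplot2::geom_rug(data = ticks,
                      ggplot2::aes(x = .data$threshold, colour = .data$slide_id),
                      sides = "b", linewidth = 1, inherit.aes = FALSE) +
    ggplot2::labs(x = channel, y = "density", colour = "slide",
                  title = sprintf("%s by slide (scale: %s)", channel, scale_tag(x))) +
    ggplot2::theme_minimal()
}

#' Plot a fitted warping function
#'
#' Shows \eqn{\phi(y)} against the identity; departures from the diagonal
#' are where the slide's intensity axis is stretched or compressed to align
#' its density with the cross-slide average.
#'
#' @param object A `warp_fn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.warp_fn <- function(object, ...) {
  df <- tibble(y = object$grid, phi = object$phi)
  ggplot2::ggplot(df, ggplot2::aes(.data$y, .data$phi)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "y", y = expression(phi(y)),
                  title = "Intensity warping function") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Dot plot of the per-channel metrics of one evaluation report (AD
#' statistic, Otsu discordance, slide variance proportion), faceted by
#' metric so channels can be compared at a glance.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(-"channel", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$channel)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(title = sprintf("Evaluation: %s", object$method),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
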