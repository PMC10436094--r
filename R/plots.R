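#' Plot a response curve with its moving average
#'
#' Points are the pointwise modelled probabilities; the line is the centred
#' moving average on which thresholds are extracted. A horizontal reference
#' marks the limiting-threshold probability.
#'
#' @param object A `tiller_curve` (or several row-bound together).
#' @param prob Reference probability line (default 0.5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tiller_curve <- function(object, prob = 0.5, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$probability,
                                   colour = .data$pd_class)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = prob, linetype = "dashed") +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = "covariate value",
                  y = "P(maximum tiller density)",
                  colour = "PD class") +
    ggplot2::theme_minimal()
}

#' Plot a candidate-ranking report
#'
#' @param object A `tiller_evaluation` from [rank_candidates()].
#' @param ... Unused.
#' @return A ggplot of held-out MAE per candidate, best first.
#' @export
autoplot.tiller_evaluation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df$mae), , drop = FALSE]
  df$candidate <- stats::reorder(df$candidate, -df$mae)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mae, y = .data$candidate,
                                   fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "held-out MAE (tillers/ha)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an out-of-season attribution table
#'
#' Full-model error versus the lowest error attainable by zeroing one
#' coefficient block, per site-year, faceted by held-out season.
#'
#' @param object A `tiller_attribution` from [attribute_errors()].
#' @param threshold Acceptable-error reference line (tillers/ha).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tiller_attribution <- function(object,
                                        threshold = attr(object, "threshold"),
                                        ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("full_error", "lowest_error"),
                            names_to = "kind", values_to = "error")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$error, y = .data$site_year,
                                        colour = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~held_out_season, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "absolute error (tillers/ha)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && !is.na(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}
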