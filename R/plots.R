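#' Plot an ICER decomposition
#'
#' Bar chart of the three additive ICER terms (drug, savings, survival)
#' with the total marked, showing which downstream components drive the
#' ratio.
#'
#' @param object A `vbp_icer` from [compute_icer()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vbp_icer <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$value,
                                   fill = .data$term)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$total, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = paste0("cost per ", object$effect_unit),
      title = paste0("ICER decomposition (", object$comparison, ", ",
                     object$horizon, " horizon)"),
      subtitle = sprintf("total ICER %.0f (dashed)", object$total)
    ) +
    ggplot2::theme_minimal()
}

#' Plot factor sensitivities and admissible ranges
#'
#' Tornado-style display of a [sensitivity_table()]: the local price
#' derivative per factor, annotated with the admissible deviation range
#' that keeps the price within tolerance.
#'
#' @param object A `vbp_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vbp_sensitivity <- function(object, ...) {
  df <- as_tibble(object)
  df$factor <- stats::reorder(df$factor, abs(df$derivative))
  df$range_label <- sprintf(
    "k in [%s, %s]",
    ifelse(df$lower_open, "open", sprintf("%.4f", df$lower)),
    ifelse(df$upper_open, "open", sprintf("%.4f", df$upper))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$derivative,
                                   y = .data$factor)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::geom_text(ggplot2::aes(label = .data$range_label),
                       hjust = -0.05, size = 3) +
    ggplot2::labs(
      x = "d(price)/dk at k = 1",
      y = NULL,
      title = "Price sensitivity to post-trial scaling factors",
      subtitle = sprintf("admissible ranges at %.0f%% price tolerance",
                         100 * df$tolerance[1])
    ) +
    ggplot2::theme_minimal()
}
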