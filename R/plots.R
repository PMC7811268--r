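# Plot helpers for composition summaries.

#' Bar plot of class composition per condition
#'
#' Mean class content with replicate-SD error bars, one bar group per
#' condition.
#'
#' @param df A lipidome table.
#' @param classes Optional subset of classes to draw.
#' @return A ggplot object.
#' @export
plot_class_composition <- function(df, classes = NULL) {
  totals <- lipid_class_totals(df) |>
    dplyr::group_by(.data$class, .data$condition) |>
    dplyr::summarise(mean = mean(.data$total), sd = stats::sd(.data$total),
                     .groups = "drop")
  if (!is.null(classes)) {
    totals <- totals |> dplyr::filter(.data$class %in% classes)
  }
  ggplot2::ggplot(totals,
                  ggplot2::aes(x = .data$class, y = .data$mean,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "Content (nmol per mg DW)",
                  fill = "Condition") +
    ggplot2::theme_minimal()
}

#' Double-bond index per condition
#'
#' @param df A lipidome table.
#' @param scope Denominator scope (default membrane lipids).
#' @return A ggplot object.
#' @export
plot_dbi <- function(df, scope = "membrane_lipids_only") {
  d <- lipid_dbi(df, scope = scope)
  aes_x <- if ("class" %in% names(d)) "class" else "condition"
  p <- ggplot2::ggplot(d,
                       ggplot2::aes(x = .data[[aes_x]], y = .data$dbi))
  if (aes_x == "class") {
    p <- p + ggplot2::aes(fill = .data$condition) +
      ggplot2::geom_col(position = "dodge")
  } else {
    p <- p + ggplot2::geom_col(width = 0.6, fill = "steelblue")
  }
  p +
    ggplot2::labs(y = "Double-bond index", x = NULL,
                  subtitle = paste("scope:", scope)) +
    ggplot2::theme_minimal()
}
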