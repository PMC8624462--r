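#' Plot a modified Bland-Altman series
#'
#' Deviation of each repetition from the subject mean, per subject, with
#' horizontal agreement limits at plus/minus two reproducibility SDs.
#'
#' @param series A `bland_altman` object from [bland_altman()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(series) {
  stopifnot(inherits(series, "bland_altman"))
  df <- unclass_df(series)
  limits <- attr(series, "limits")
  ggplot2::ggplot(df, ggplot2::aes(x = subject_id,
                                   y = deviation,
                                   colour = operator_id)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "blue") +
    ggplot2::geom_hline(yintercept = limits, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(
      title = paste0(attr(series, "landmark"), " (",
                     attr(series, "axis"), " axis)"),
      x = "subject", y = "deviation from subject mean (mm)",
      colour = "operator") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

# Same plot from a slice of the combined pipeline data frame.
plot_bland_altman_df <- function(df, landmark, axis) {
  ggplot2::ggplot(df, ggplot2::aes(x = subject_id,
                                   y = deviation,
                                   colour = operator_id)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * df$limit[1],
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(title = paste0(landmark, " (", axis, " axis)"),
                  x = "subject",
                  y = "deviation from subject mean (mm)",
                  colour = "operator") +
    ggplot2::theme_minimal()
}
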