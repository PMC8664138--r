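# autoplot() methods for the result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.vnc_grid <- function(object, ...) {
  df <- object$results
  df$conc_label <- factor(sprintf("%g mg/ml", df$conc_mg_ml),
                          levels = sprintf("%g mg/ml",
                                           sort(unique(df$conc_mg_ml))))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$workflow),
                                   y = .data$conc_error,
                                   fill = .data$conc_label)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "workflow",
      y = sprintf("%s concentration error (mg/ml)", object$material),
      fill = NULL,
      title = sprintf("%s: concentration errors by workflow (manual method)",
                      object$modality)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.der_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$hu_high,
                                            y = .data$hu_low)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$der,
                         linetype = 2) +
    ggplot2::labs(x = "high-energy HU", y = "low-energy HU",
                  title = sprintf("DER fit: slope = %.3f", object$der)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.noise_study <- function(object, ...) {
  ggplot2::ggplot(object$insert_means,
                  ggplot2::aes(x = .data$insert, y = .data$mean,
                               fill = .data$arm)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "VNC insert mean (HU)", fill = NULL,
                  title = sprintf("%s noise study: insert means by arm",
                                  object$modality)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
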