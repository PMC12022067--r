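#' @export
autoplot.cognilr_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "Receiver operating characteristic") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cognilr_cv <- function(object, bins = 20, ...) {
  ggplot2::ggplot(object$auc, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$cv_mean_auc, linetype = "dashed") +
    ggplot2::labs(
      x = "Test AUC", y = "Repetitions",
      title = sprintf("Cross-validated AUC: %.2f ± %.2f sd",
                      object$cv_mean_auc, object$cv_sd_auc)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cognilr_priors <- function(object, ...) {
  df <- as_tibble(object)
  df$bracket <- sprintf("[%g,%g)", df$bracket_lo, df$bracket_hi)
  df$bracket <- factor(df$bracket, levels = df$bracket)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bracket, y = .data$prior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = overall_prior(object), linetype = "dashed") +
    ggplot2::labs(x = "Age of onset bracket (years)",
                  y = "Prior probability of decline",
                  title = "Age-bracket prior probabilities") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sensitivity/specificity across decision cutoffs
#'
#' Plots sensitivity and specificity of thresholded posteriors over the
#' whole range of probability cutoffs.
#'
#' @param scores Posterior probabilities.
#' @param labels 0/1 or logical outcome labels.
#' @return A ggplot object.
#' @export
plot_cutoff_performance <- function(scores, labels) {
  labels <- as.logical(labels)
  cuts <- sort(unique(c(0, scores, 1)))
  df <- purrr::map(cuts, function(ct) {
    m <- confusion_metrics(scores >= ct, labels)
    tibble(cutoff = ct, sensitivity = m$sensitivity, specificity = m$specificity)
  }) %>%
    bind_rows() %>%
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                   linetype = .data$metric)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Probability cutoff", y = NULL) +
    ggplot2::theme_minimal()
}
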