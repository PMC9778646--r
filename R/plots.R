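#' Observed versus predicted counts for a fitted network
#'
#' Scatter of predicted against observed counts, one panel per analyte,
#' with the identity line; points are coloured by data split.
#'
#' @param object An `mlp_fit` from [train_mlp()].
#' @param data The sample table the model was fitted on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mlp_fit <- function(object, data, ...) {
  pred <- predict(object, data)
  split_of <- rep(NA_character_, nrow(data))
  for (s in names(object$splits)) split_of[object$splits[[s]]] <- s
  long <- purrr::map_dfr(output_names(), function(a) {
    tibble::tibble(analyte = a, observed = data[[a]],
                   predicted = pred[[a]], split = split_of)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$observed,
                                     y = .data$predicted,
                                     colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte), scales = "free") +
    ggplot2::labs(x = "observed (log10 CFU/g)",
                  y = "predicted (log10 CFU/g)") +
    ggplot2::theme_minimal()
}

#' Stacked class-percentage bar chart
#'
#' @param class_summary Output of [summarize_classes()].
#' @return A ggplot object.
#' @export
plot_class_summary <- function(class_summary) {
  long <- tidyr::pivot_longer(class_summary,
                              dplyr::starts_with("percent_"),
                              names_to = "class", names_prefix = "percent_",
                              values_to = "percent")
  long$class <- factor(long$class, levels = rev(class_levels()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$analyte, y = .data$percent,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(unsatisfactory = "#c0392b",
                                          acceptable = "#f1c40f",
                                          satisfactory = "#27ae60")) +
    ggplot2::labs(x = NULL, y = "% of samples", fill = NULL) +
    ggplot2::theme_minimal()
}

#' LAB frequency histogram
#'
#' @param lab_frequency Output of [bin_lab()].
#' @return A ggplot object.
#' @export
plot_lab_frequency <- function(lab_frequency) {
  ggplot2::ggplot(lab_frequency,
                  ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "#2980b9") +
    ggplot2::labs(x = "LAB (log10 CFU/g)", y = "samples") +
    ggplot2::theme_minimal()
}
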