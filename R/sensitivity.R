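#' Yoon connection-weight importance of each input for each output
#'
#' Yoon's interpretation method scores input `i` for output `k` by the sum
#' over hidden units of the products of the input-to-hidden and
#' hidden-to-output weights,
#' \eqn{s(i,k) = \sum_j W_1[j,i] \, W_2[k,j]}
#' (biases and activations are excluded), and expresses it as a signed
#' relative importance
#' \eqn{RI(i,k) = 100 \, s(i,k) / \sum_{i'} |s(i',k)|}
#' so that the absolute importances for each output sum to 100 percent.
#' The sign tells whether the input pushes the output up or down; the
#' measure is invariant to positive rescaling of either weight matrix and
#' to permuting hidden units.
#'
#' @param params An [mlp_parameters()] object, e.g. from
#'   [load_published_weights()] or a [train_mlp()] fit (`fit$params`).
#' @return A tibble of class `yoon_importance` in long format: `input`,
#'   `output` (factors in network order), raw `score` and `importance`
#'   (signed percent).
#' @export
#' @examples
#' imp <- yoon_importance(load_published_weights())
#' importance_matrix(imp)
yoon_importance <- function(params) {
  s <- t(params$W1) %*% t(params$W2)  # inputs x outputs
  denom <- colSums(abs(s))
  if (any(denom == 0)) {
    zero <- which(denom == 0)
    labels <- params$output_labels %||% as.character(zero)
    abort(paste0("importance undefined: all-zero scores for output(s) ",
                 paste(labels[zero], collapse = ", ")))
  }
  ri <- 100 * sweep(s, 2, denom, `/`)
  in_labels <- params$input_labels %||% paste0("input_", seq_len(nrow(s)))
  out_labels <- params$output_labels %||% paste0("output_", seq_len(ncol(s)))
  out <- tidyr::expand_grid(
    output = factor(out_labels, levels = out_labels),
    input = factor(in_labels, levels = in_labels)
  )
  # expand_grid varies `input` fastest: column-major order of inputs x outputs
  out$score <- as.vector(s)
  out$importance <- as.vector(ri)
  out <- out[, c("input", "output", "score", "importance")]
  class(out) <- c("yoon_importance", class(out))
  out
}

#' Reshape an importance table to an inputs-by-outputs matrix
#'
#' @param importance A `yoon_importance` tibble from [yoon_importance()].
#' @return Numeric matrix of signed percent importances, inputs in rows.
#' @export
importance_matrix <- function(importance) {
  wide <- tidyr::pivot_wider(importance[, c("input", "output", "importance")],
                             names_from = "output",
                             values_from = "importance")
  m <- as.matrix(wide[, -1])
  rownames(m) <- as.character(wide$input)
  m
}

#' Ranked per-output importance listing
#'
#' For each output, inputs are sorted by signed importance (most positive
#' first) and the extremes are flagged: `is_top` marks the most positive
#' driver, `is_bottom` the most negative.
#'
#' @param importance A `yoon_importance` tibble.
#' @return A tibble with `output`, `rank`, `input`, `importance`,
#'   `is_top`, `is_bottom`.
#' @export
#' @examples
#' importance_report(yoon_importance(load_published_weights()))
importance_report <- function(importance) {
  importance |>
    dplyr::group_by(.data$output) |>
    dplyr::arrange(dplyr::desc(.data$importance), .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      is_top = .data$rank == 1,
      is_bottom = .data$rank == dplyr::n()
    ) |>
    dplyr::ungroup() |>
    dplyr::select("output", "rank", "input", "importance",
                  "is_top", "is_bottom")
}

#' Plot signed Yoon importances
#'
#' Horizontal bar chart of signed relative importance, one panel per
#' output.
#'
#' @param object A `yoon_importance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yoon_importance <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$importance,
                               y = forcats_rev(.data$input),
                               fill = .data$importance > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$output)) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "relative importance (%)", y = NULL) +
    ggplot2::theme_minimal()
}

# reverse factor levels without depending on forcats
forcats_rev <- function(f) factor(f, levels = rev(levels(f)))
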