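#' Plot reconstructed influence against susceptibility
#'
#' Scatter of the per-node scores on square-root axes (both scores are
#' heavy-tailed); useful for eyeballing the influence/susceptibility
#' anticorrelation and the sparsity of the jointly-high corner.
#'
#' @param object An `is_scores` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.is_scores <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$influence,
                                 y = .data$susceptibility)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::scale_x_sqrt() +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "influence (reconstructed)",
                  y = "susceptibility (reconstructed)",
                  title = "Reconstructed node traits") +
    ggplot2::theme_minimal()
}

#' Plot a null distribution with its observed statistic
#'
#' @param object A `null_result` from [randomized_null()].
#' @param ... Unused.
#' @return A ggplot: histogram of the rewired-network statistic values with
#'   the observed value marked.
#' @export
autoplot.null_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 25, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic, y = "replicates",
      title = sprintf("Randomized-network null (p = %.3f)", object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Compare prediction models across windows
#'
#' @param results Tibble from [rolling_experiment()].
#' @param metric `"auprc"` or `"precision_at_k"`.
#' @return A ggplot with one bar per model, averaged over seeds, faceted by
#'   window pair.
#' @export
plot_model_comparison <- function(results, metric = c("auprc",
                                                      "precision_at_k")) {
  metric <- match.arg(metric)
  results |>
    group_by(.data$window, .data$model) |>
    summarise(value = mean(.data[[metric]]), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$model, y = .data$value,
                                 fill = .data$model)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$window), labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
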