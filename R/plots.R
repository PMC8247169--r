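#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an intersection enrichment grid
#'
#' Enriched pairs are drawn by their -log10(p) display value; depleted pairs
#' at zero (the display convention of the source analysis).
#'
#' @param object An `enrichment_grid` from [intersection_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_grid
#' @export
autoplot.enrichment_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region, y = .data$cell_type,
                                       fill = .data$display)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "firebrick",
                                 name = expression(-log[10](p))) +
    ggplot2::labs(x = "spatial region", y = "cell type") +
    ggplot2::theme_minimal()
}

#' Heatmap of destination proportions for a transition comparison
#'
#' @param object A `transition_summary` from [transition_contingency()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transition_summary
#' @export
autoplot.transition_summary <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$destination, y = .data$condition,
                               fill = .data$prop)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prop)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkorange",
                                 name = "proportion") +
    ggplot2::labs(x = "destination state",
                  y = "condition",
                  title = paste("transitions from", object$source_state)) +
    ggplot2::theme_minimal()
}

#' Per-cell aggregate CNV signal by group
#'
#' @param object A `cnv_matrix` from [infer_cnv()].
#' @param ... Unused.
#' @return A ggplot (violin of the aggregate signal, reference vs query).
#' @method autoplot cnv_matrix
#' @export
autoplot.cnv_matrix <- function(object, ...) {
  dat <- dplyr::mutate(object$aggregate,
                       set = ifelse(.data$reference, "reference", "query"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$set, y = .data$cnv_signal)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, size = 0.3, alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "mean squared CNV window score") +
    ggplot2::theme_minimal()
}

#' Scores of each signature across assigned states
#'
#' @param scores Tibble from [score_signatures()].
#' @param states Tibble from [assign_state_by_max()].
#' @return A ggplot (violin per signature and state).
#' @export
plot_state_scores <- function(scores, states) {
  long <- scores |>
    dplyr::left_join(states[c("cell_id", "state")], by = "cell_id") |>
    tidyr::pivot_longer(-c("cell_id", "state"), names_to = "signature",
                        values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$score)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::facet_wrap(~signature) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
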