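#' Degree versus redundancy scatter of miR nodes
#'
#' The classification plane of the commodore criterion: miR nodes plotted by
#' degree (log10 x-axis) and redundancy coefficient, with dashed guides at
#' the thresholds. Commodores occupy the high-degree, low-redundancy
#' quadrant. If `metrics` carries a `subtype` column the points are coloured
#' by it.
#'
#' @param metrics Node metrics tibble (from [node_metrics()] or the pipeline
#'   bundle); nodes with undefined redundancy are dropped.
#' @param k_min,rc_max Thresholds to draw (defaults 100 and 0.5).
#' @return A ggplot object.
#' @export
plot_degree_redundancy <- function(metrics, k_min = 100, rc_max = 0.5) {
  d <- dplyr::filter(metrics, .data$layer == "miR", !is.na(.data$redundancy))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, y = .data$redundancy))
  p <- if ("subtype" %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$subtype), alpha = 0.7)
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::geom_vline(xintercept = k_min, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = rc_max, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "degree k", y = "redundancy coefficient rc",
                  title = "miR connectivity vs redundancy") +
    ggplot2::theme_minimal()
}

#' @rdname plot_degree_redundancy
#' @param object A [bipartite_network()]; its node metrics are plotted.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.bipartite_network <- function(object, k_min = 100, rc_max = 0.5, ...) {
  plot_degree_redundancy(node_metrics(object), k_min = k_min, rc_max = rc_max)
}

#' Heatmap of neighbourhood Jaccard similarity
#'
#' @param jaccard Symmetric matrix from [neighborhood_jaccard()].
#' @return A ggplot object.
#' @export
plot_neighborhood_similarity <- function(jaccard) {
  d <- tibble::as_tibble(jaccard, rownames = "a") |>
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "jaccard")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                  fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of top enriched terms
#'
#' @param enrichment Tibble from [enrich_neighborhood()].
#' @param top_n Number of terms to show (default 20).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top_n = 20) {
  d <- dplyr::slice_min(enrichment, .data$adj_p_value, n = top_n,
                        with_ties = FALSE)
  lab <- if ("name" %in% names(d)) d$name else d$term_id
  d$label <- factor(lab, levels = rev(lab))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$adj_p_value),
                                  y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL) +
    ggplot2::theme_minimal()
}
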