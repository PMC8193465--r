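#' Tidy the full miR-gene MI score set
#'
#' @param x An `mi_scores` object.
#' @param ... Unused.
#' @return Tibble with one row per scored pair: `mir_id`, `gene_id`, `mi`.
#' @export
tidy.mi_scores <- function(x, ...) {
  tibble::tibble(
    mir_id = rep(x$mir_ids, times = length(x$gene_ids)),
    gene_id = rep(x$gene_ids, each = length(x$mir_ids)),
    mi = as.vector(x$mi)
  )
}

#' Tidy a bipartite network into its edge list
#'
#' @param x A [bipartite_network()].
#' @param ... Unused.
#' @return Edge tibble (`mir_id`, `gene_id`, `mi`).
#' @export
tidy.bipartite_network <- function(x, ...) x$edges

#' One-row network summary
#'
#' @param x A [bipartite_network()].
#' @param ... Unused.
#' @return Tibble with connected-node counts per layer, edges, components,
#'   threshold and quantile.
#' @export
glance.bipartite_network <- function(x, ...) {
  dplyr::mutate(network_summary(x), threshold = x$threshold,
                quantile = x$quantile)
}
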