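#' Classify commodore miRs
#'
#' A commodore miR is a miR-layer node that is highly connected but
#' non-redundant: degree `k >= k_min` and redundancy coefficient
#' `rc <= rc_max`, both comparisons inclusive. Gene-layer nodes are never
#' classified, and nodes with undefined redundancy (degree < 2) never
#' qualify. An empty result is valid — some phenotypes have no commodore.
#'
#' @param metrics Node metrics tibble from [node_metrics()].
#' @param k_min Minimum degree (default 100).
#' @param rc_max Maximum redundancy coefficient (default 0.5).
#' @return Tibble with columns `mir_id`, `degree`, `redundancy`.
#' @export
classify_commodores <- function(metrics, k_min = 100, rc_max = 0.5) {
  stopifnot(is.data.frame(metrics),
            all(c("node_id", "layer", "degree", "redundancy") %in% names(metrics)))
  metrics |>
    dplyr::filter(.data$layer == "miR",
                  .data$degree >= k_min,
                  !is.na(.data$redundancy),
                  .data$redundancy <= rc_max) |>
    dplyr::transmute(mir_id = .data$node_id, degree = .data$degree,
                     redundancy = .data$redundancy) |>
    dplyr::arrange(.data$mir_id)
}

#' Gene neighbourhood of a miR
#'
#' @param net A [bipartite_network()].
#' @param mir_id miR node identifier.
#' @return Character vector (sorted) of adjacent gene ids; length equals the
#'   miR's degree.
#' @export
mir_neighborhood <- function(net, mir_id) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!mir_id %in% net$mir_nodes) {
    stop("unknown miR: ", mir_id, call. = FALSE)
  }
  sort(net$edges$gene_id[net$edges$mir_id == mir_id])
}

#' Commodore records with gene neighbourhoods
#'
#' Classifies commodores on a network and attaches each one's gene
#' neighbourhood; records are keyed by (`mir_id`, `subtype`) so the same miR
#' can be a commodore in several phenotypes.
#'
#' @param net A [bipartite_network()].
#' @param subtype Phenotype label to attach to each record.
#' @inheritParams classify_commodores
#' @return Tibble with columns `subtype`, `mir_id`, `degree`, `redundancy`
#'   and the list-column `neighborhood`.
#' @export
commodore_records <- function(net, subtype = NA_character_, k_min = 100, rc_max = 0.5) {
  cds <- classify_commodores(node_metrics(net), k_min = k_min, rc_max = rc_max)
  tibble::tibble(
    subtype = rep(subtype, nrow(cds)),
    mir_id = cds$mir_id,
    degree = cds$degree,
    redundancy = cds$redundancy,
    neighborhood = purrr::map(cds$mir_id, ~ mir_neighborhood(net, .x))
  )
}

#' Jaccard similarity between commodore neighbourhoods
#'
#' J(A, B) = |A intersect B| / |A union B|; the diagonal is 1 and the matrix
#' is symmetric. Two empty sets are assigned similarity 0 off-diagonal.
#'
#' @param neighborhoods Named list of gene-id character vectors, or a
#'   commodore record tibble from [commodore_records()] (names are then
#'   `subtype:mir_id` or plain `mir_id`).
#' @return Symmetric numeric matrix in `[0, 1]`.
#' @export
neighborhood_jaccard <- function(neighborhoods) {
  if (is.data.frame(neighborhoods)) {
    labs <- if (all(is.na(neighborhoods$subtype))) neighborhoods$mir_id else
      paste(neighborhoods$subtype, neighborhoods$mir_id, sep = ":")
    neighborhoods <- setNames(neighborhoods$neighborhood, labs)
  }
  stopifnot(length(neighborhoods) >= 1)
  n <- length(neighborhoods)
  sets <- lapply(neighborhoods, unique)
  out <- diag(1, n)
  dimnames(out) <- list(names(neighborhoods), names(neighborhoods))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        u <- length(union(sets[[i]], sets[[j]]))
        out[i, j] <- out[j, i] <-
          if (u == 0) 0 else length(intersect(sets[[i]], sets[[j]])) / u
      }
    }
  }
  out
}
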