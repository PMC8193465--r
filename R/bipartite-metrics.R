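# sparse adjacency (genes x miRs) of a bipartite network
adjacency_sparse <- function(net) {
  gi <- match(net$edges$gene_id, net$gene_nodes)
  mi <- match(net$edges$mir_id, net$mir_nodes)
  Matrix::sparseMatrix(
    i = gi, j = mi, x = 1,
    dims = c(length(net$gene_nodes), length(net$mir_nodes)),
    dimnames = list(net$gene_nodes, net$mir_nodes)
  )
}

#' Node degree in a bipartite network
#'
#' @param net A [bipartite_network()].
#' @param node_id Node identifier (either layer).
#' @return Number of incident cross-layer edges.
#' @export
node_degree <- function(net, node_id) {
  stopifnot(inherits(net, "bipartite_network"))
  if (node_id %in% net$mir_nodes) {
    sum(net$edges$mir_id == node_id)
  } else if (node_id %in% net$gene_nodes) {
    sum(net$edges$gene_id == node_id)
  } else {
    stop("unknown node: ", node_id, call. = FALSE)
  }
}

#' Bipartite redundancy coefficient
#'
#' For a node v with neighbours N(v) in the opposite layer, the redundancy
#' coefficient is the fraction of neighbour pairs \{u, w\} that are both
#' linked to some other node v' of v's layer — i.e. the pairs that remain
#' co-connected if v is removed. It is undefined for degree < 2 (no neighbour
#' pairs), in which case `NA` is returned rather than 0.
#'
#' @param net A [bipartite_network()].
#' @param node_id Node identifier.
#' @return Redundancy in `[0, 1]`, or `NA_real_` when degree < 2.
#' @export
redundancy_coefficient <- function(net, node_id) {
  stopifnot(inherits(net, "bipartite_network"))
  A <- adjacency_sparse(net) # genes x miRs
  if (node_id %in% net$mir_nodes) {
    redundancy_from_adjacency(A, match(node_id, net$mir_nodes))
  } else if (node_id %in% net$gene_nodes) {
    redundancy_from_adjacency(Matrix::t(A), match(node_id, net$gene_nodes))
  } else {
    stop("unknown node: ", node_id, call. = FALSE)
  }
}

# A: neighbours-of-v layer in rows, v's layer in columns; j: column of v
redundancy_from_adjacency <- function(A, j) {
  nb <- which(A[, j] != 0)
  k <- length(nb)
  if (k < 2) return(NA_real_)
  S <- A[nb, -j, drop = FALSE]
  # pair {u,w} covered iff some remaining column links both
  P <- Matrix::tcrossprod(S)
  covered <- (sum(P > 0) - sum(Matrix::diag(P) > 0)) / 2
  covered / choose(k, 2)
}

#' Per-node metrics table
#'
#' Degree and redundancy coefficient for every node of the network;
#' redundancy is `NA` where undefined (degree < 2).
#'
#' @param net A [bipartite_network()].
#' @return Tibble with columns `node_id`, `layer`, `degree`, `redundancy`.
#' @export
node_metrics <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  A <- adjacency_sparse(net)
  At <- Matrix::t(A)
  mir_deg <- Matrix::colSums(A)
  gene_deg <- Matrix::rowSums(A)
  rc_layer <- function(M, deg) {
    # M: opposite layer x own layer; rc undefined below degree 2
    vapply(seq_len(ncol(M)), function(j) {
      if (deg[j] < 2) NA_real_ else redundancy_from_adjacency(M, j)
    }, numeric(1))
  }
  tibble::tibble(
    node_id = c(net$mir_nodes, net$gene_nodes),
    layer = rep(c("miR", "gene"), c(length(net$mir_nodes), length(net$gene_nodes))),
    degree = as.integer(c(mir_deg, gene_deg)),
    redundancy = c(rc_layer(A, mir_deg), rc_layer(At, gene_deg))
  )
}

#' Connected components among non-isolated nodes
#'
#' Partitions the nodes with degree > 0 into maximal connected sets; isolated
#' nodes are excluded, matching the convention of counting components over
#' non-single nodes.
#'
#' @param net A [bipartite_network()].
#' @return Tibble with columns `node_id`, `layer`, `component`.
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (nrow(net$edges) == 0) {
    return(tibble::tibble(node_id = character(), layer = character(),
                          component = integer()))
  }
  g <- as_igraph(net, connected_only = TRUE)
  comp <- igraph::components(g)
  tibble::tibble(
    node_id = igraph::V(g)$name,
    layer = igraph::V(g)$layer,
    component = as.integer(comp$membership)
  )
}

#' Network summary
#'
#' The per-layer connected-node counts (degree > 0), edge count and number of
#' connected components among non-isolated nodes.
#'
#' @param net A [bipartite_network()].
#' @return One-row tibble with columns `connected_mirs`, `connected_genes`,
#'   `edges`, `components`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  comp <- connected_components(net)
  tibble::tibble(
    connected_mirs = length(unique(net$edges$mir_id)),
    connected_genes = length(unique(net$edges$gene_id)),
    edges = nrow(net$edges),
    components = if (nrow(comp) == 0) 0L else max(comp$component)
  )
}

#' Degree distribution of a network
#'
#' @param net A [bipartite_network()].
#' @return Tibble with columns `layer`, `degree`, `n_nodes`.
#' @export
degree_distribution <- function(net) {
  m <- node_metrics(net)
  dplyr::count(m, .data$layer, .data$degree, name = "n_nodes")
}
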