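#' Equal-frequency discretization
#'
#' Rank-based binning into `n_bins` equal-frequency bins. When all values are
#' distinct, bin sizes differ by at most one; tied values always share a
#' single bin (minimum-rank convention), so the labels are invariant under
#' any strictly monotone transform of `x`.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins, `2 <= n_bins <= length(x)`.
#' @return Integer bin labels in `1..n_bins`.
#' @export
discretize_equal_frequency <- function(x, n_bins) {
  n <- length(x)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (n_bins > n) stop("n_bins may not exceed length(x)", call. = FALSE)
  if (anyNA(x)) stop("x must not contain missing values", call. = FALSE)
  r <- rank(x, ties.method = "min")
  as.integer(ceiling(r * n_bins / n))
}

#' Plug-in mutual information on equal-frequency bins
#'
#' Estimates MI in bits between two expression profiles by discretizing each
#' into `n_bins` equal-frequency bins and applying the plug-in estimator
#' \deqn{\hat I = \sum_{ij} \hat p_{ij} \log_2 \frac{\hat p_{ij}}{\hat p_{i\cdot}\hat p_{\cdot j}}.}
#' The estimate is nonnegative, symmetric in its arguments, and invariant
#' under strictly monotone transforms of either input.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @param n_bins Number of bins; defaults to `floor(sqrt(length(x)))`.
#' @return MI estimate in bits.
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("at least 4 observations are required", call. = FALSE)
  if (min(x) == max(x) || min(y) == max(y)) {
    stop("mutual information is undefined for a constant vector", call. = FALSE)
  }
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(n)))
  lx <- discretize_equal_frequency(x, n_bins)
  ly <- discretize_equal_frequency(y, n_bins)
  joint <- table(factor(lx, levels = seq_len(n_bins)),
                 factor(ly, levels = seq_len(n_bins))) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  max(0, sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz])))
}

#' Score all miR-gene pairs by mutual information
#'
#' Computes the plug-in MI estimate for every pair of one miR and one gene
#' transcript over a shared, identically ordered sample set. Zero-variance
#' transcripts (which cannot be binned) are dropped with a warning; the
#' recorded total pair count refers to the retained transcripts and defines
#' the denominator for quantile thresholding.
#'
#' @param mir,gene Expression tibbles of the miR and gene layer over the same
#'   samples in the same order.
#' @param n_bins Number of equal-frequency bins; defaults to
#'   `floor(sqrt(n_samples))`.
#' @return An object of class `mi_scores`: the MI matrix (miRs by genes) plus
#'   retained ids, bin count and total pair count. Use [tidy()] for the
#'   per-pair tibble.
#' @export
mi_scores <- function(mir, gene, n_bins = NULL) {
  ms <- setdiff(names(mir), "transcript_id")
  gs <- setdiff(names(gene), "transcript_id")
  if (!identical(ms, gs)) {
    stop("miR and gene tables must share an identically ordered sample set",
         call. = FALSE)
  }
  n <- length(ms)
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(n)))
  if (n_bins < 2 || n_bins > n) stop("invalid n_bins", call. = FALSE)

  mv <- expression_values(mir)
  gv <- expression_values(gene)
  keep_row <- function(m) apply(m, 1, function(r) min(r) != max(r))
  km <- keep_row(mv); kg <- keep_row(gv)
  if (!all(km) || !all(kg)) {
    warning("dropped ", sum(!km), " constant miR(s) and ", sum(!kg),
            " constant gene(s) before MI scoring", call. = FALSE)
    mv <- mv[km, , drop = FALSE]
    gv <- gv[kg, , drop = FALSE]
  }
  if (nrow(mv) == 0 || nrow(gv) == 0) stop("no transcripts left to score", call. = FALSE)

  # samples in rows so the C++ kernel walks contiguous memory
  ml <- discretize_columns(t(mv), n_bins)
  gl <- discretize_columns(t(gv), n_bins)
  mi <- mi_all_pairs_labels(ml, gl, n_bins)
  dimnames(mi) <- list(rownames(mv), rownames(gv))

  structure(
    list(
      mi = mi,
      mir_ids = rownames(mv),
      gene_ids = rownames(gv),
      n_bins = as.integer(n_bins),
      n_samples = n,
      total_pairs = nrow(mv) * nrow(gv)
    ),
    class = "mi_scores"
  )
}

#' @export
print.mi_scores <- function(x, ...) {
  cat("<mi_scores> ", length(x$mir_ids), " miRs x ", length(x$gene_ids),
      " genes (", x$total_pairs, " pairs), ", x$n_bins, " bins, ",
      x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Construct a bipartite miR-gene network
#'
#' Low-level constructor used by [threshold_network()] and by tests: edges
#' connect the miR layer to the gene layer only.
#'
#' @param edges Tibble with columns `mir_id`, `gene_id` and optionally `mi`.
#' @param mir_nodes,gene_nodes Full node sets per layer (default: the ids
#'   occurring in `edges`); nodes without a retained edge have degree 0.
#' @param threshold,quantile Threshold value and quantile used to build the
#'   network (NA when constructed directly).
#' @return An object of class `bipartite_network`.
#' @export
bipartite_network <- function(edges, mir_nodes = NULL, gene_nodes = NULL,
                              threshold = NA_real_, quantile = NA_real_) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("mir_id", "gene_id") %in% names(edges)))
  if (!"mi" %in% names(edges)) edges$mi <- NA_real_
  if (is.null(mir_nodes)) mir_nodes <- unique(edges$mir_id)
  if (is.null(gene_nodes)) gene_nodes <- unique(edges$gene_id)
  if (length(intersect(mir_nodes, gene_nodes)) > 0) {
    stop("miR and gene node ids must be disjoint", call. = FALSE)
  }
  if (!all(edges$mir_id %in% mir_nodes) || !all(edges$gene_id %in% gene_nodes)) {
    stop("every edge must join a miR node to a gene node", call. = FALSE)
  }
  if (anyDuplicated(paste(edges$mir_id, edges$gene_id))) {
    stop("duplicate edges", call. = FALSE)
  }
  structure(
    list(
      edges = edges[c("mir_id", "gene_id", "mi")],
      mir_nodes = as.character(mir_nodes),
      gene_nodes = as.character(gene_nodes),
      threshold = threshold,
      quantile = quantile
    ),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("<bipartite_network> ", length(x$mir_nodes), " miR nodes, ",
      length(x$gene_nodes), " gene nodes, ", nrow(x$edges), " edges",
      if (!is.na(x$threshold)) paste0(" (MI >= ", signif(x$threshold, 6),
                                      ", quantile ", x$quantile) else "",
      if (!is.na(x$threshold)) ")" else "", "\n", sep = "")
  invisible(x)
}

#' Threshold MI scores at a global upper quantile
#'
#' Keeps the top `1 - quantile` fraction of all scored pairs as network
#' edges: with `m = ceiling((1 - quantile) * total_pairs)`, the threshold is
#' the m-th largest score and every pair scoring at or above it becomes an
#' edge. No tie-breaking is applied, so ties at the threshold can push the
#' edge count above `m`. Nodes that lose all their edges are retained in the
#' node sets with degree zero.
#'
#' @param scores An `mi_scores` object.
#' @param quantile Upper quantile in (0, 1); default 0.9999.
#' @return A [bipartite_network()].
#' @export
threshold_network <- function(scores, quantile = 0.9999) {
  stopifnot(inherits(scores, "mi_scores"))
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1) {
    stop("quantile must lie strictly between 0 and 1", call. = FALSE)
  }
  v <- scores$mi
  if (length(v) == 0) stop("empty score set", call. = FALSE)
  m <- ceiling((1 - quantile) * scores$total_pairs)
  m <- max(1L, min(m, length(v)))
  pos <- length(v) - m + 1L # m-th largest via partial sort
  thr <- sort(v, partial = pos)[pos]
  if (min(v) == max(v)) {
    warning("all MI scores are equal; every pair becomes an edge", call. = FALSE)
  }
  idx <- which(v >= thr, arr.ind = TRUE)
  edges <- tibble::tibble(
    mir_id = scores$mir_ids[idx[, 1]],
    gene_id = scores$gene_ids[idx[, 2]],
    mi = v[idx]
  )
  edges <- dplyr::arrange(edges, dplyr::desc(.data$mi), .data$mir_id, .data$gene_id)
  bipartite_network(edges, scores$mir_ids, scores$gene_ids,
                    threshold = thr, quantile = quantile)
}

#' Convert a bipartite network to an igraph graph
#'
#' @param net A [bipartite_network()].
#' @param connected_only Drop degree-zero nodes first?
#' @return An `igraph` graph with a `layer` vertex attribute.
#' @export
as_igraph <- function(net, connected_only = FALSE) {
  stopifnot(inherits(net, "bipartite_network"))
  verts <- tibble::tibble(
    name = c(net$mir_nodes, net$gene_nodes),
    layer = rep(c("miR", "gene"), c(length(net$mir_nodes), length(net$gene_nodes)))
  )
  if (connected_only) {
    used <- unique(c(net$edges$mir_id, net$edges$gene_id))
    verts <- verts[verts$name %in% used, ]
  }
  igraph::graph_from_data_frame(
    net$edges[c("mir_id", "gene_id", "mi")],
    directed = FALSE, vertices = verts
  )
}

#' Write a network edge list / GraphML file
#'
#' @param net A [bipartite_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(net$edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
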