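# Independent oracles used to cross-check the implementation. These are
# deliberately naive (explicit loops, full enumeration) and share no code
# with the package internals.

# plug-in histogram MI in bits, explicit cell loops
oracle_mi <- function(x, y, n_bins) {
  n <- length(x)
  bin_of <- function(v) {
    r <- rank(v, ties.method = "min")
    ceiling(r * n_bins / n)
  }
  bx <- bin_of(x); by <- bin_of(y)
  mi <- 0
  for (i in seq_len(n_bins)) {
    for (j in seq_len(n_bins)) {
      nij <- sum(bx == i & by == j)
      if (nij == 0) next
      ni <- sum(bx == i); nj <- sum(by == j)
      mi <- mi + (nij / n) * log2((nij * n) / (ni * nj))
    }
  }
  mi
}

# brute-force bipartite redundancy: loop over all neighbour pairs and all
# candidate covering nodes of v's own layer
oracle_redundancy <- function(edges, node, own_col, opp_col) {
  nb <- edges[[opp_col]][edges[[own_col]] == node]
  k <- length(nb)
  if (k < 2) return(NA_real_)
  others <- setdiff(unique(edges[[own_col]]), node)
  covered <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      hit <- FALSE
      for (o in others) {
        onb <- edges[[opp_col]][edges[[own_col]] == o]
        if (nb[i] %in% onb && nb[j] %in% onb) { hit <- TRUE; break }
      }
      if (hit) covered <- covered + 1
    }
  }
  covered / choose(k, 2)
}

# flood-fill component count over non-isolated nodes of an edge list
oracle_components <- function(edges) {
  if (nrow(edges) == 0) return(0L)
  nodes <- unique(c(edges$mir_id, edges$gene_id))
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- c(edges$gene_id[edges$mir_id == v], edges$mir_id[edges$gene_id == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  cur
}

# hypergeometric upper tail by direct summation of choose() terms
oracle_hypergeom <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Wang S-values by enumerating every upward path and taking the max
# product of edge weights along it
oracle_svalues <- function(term, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  best <- c(1); names(best) <- term
  walk <- function(node, value) {
    up <- dag[dag$child_id == node, ]
    for (i in seq_len(nrow(up))) {
      p <- up$parent_id[i]
      v <- value * weights[[up$edge_type[i]]]
      if (is.na(best[p]) || v > best[[p]]) best[p] <<- v
      walk(p, v)
    }
  }
  walk(term, 1)
  best
}

# random bipartite edge list with nm miR and ng gene nodes
random_bipartite_edges <- function(nm, ng, p = 0.4) {
  mirs <- paste0("m", seq_len(nm))
  genes <- paste0("g", seq_len(ng))
  grid <- expand.grid(mir_id = mirs, gene_id = genes,
                      stringsAsFactors = FALSE)
  grid[runif(nrow(grid)) < p, ]
}

# random single-rooted DAG over n terms with mixed edge types
random_dag <- function(n_terms) {
  ids <- paste0("t", seq_len(n_terms))
  rows <- lapply(2:n_terms, function(i) {
    np <- sample(1:min(2, i - 1), 1)
    data.frame(child_id = ids[i],
               parent_id = sample(ids[seq_len(i - 1)], np),
               edge_type = sample(c("is_a", "part_of"), np, replace = TRUE))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# mi_scores stub carrying an arbitrary score matrix (for threshold tests)
make_scores <- function(mat) {
  structure(
    list(mi = mat,
         mir_ids = if (is.null(rownames(mat))) paste0("m", seq_len(nrow(mat))) else rownames(mat),
         gene_ids = if (is.null(colnames(mat))) paste0("g", seq_len(ncol(mat))) else colnames(mat),
         n_bins = 2L, n_samples = 4L,
         total_pairs = length(mat)),
    class = "mi_scores"
  )
}

expect_rc_matches_oracle <- function(edges) {
  net <- bipartite_network(tibble::as_tibble(edges),
                           mir_nodes = unique(edges$mir_id),
                           gene_nodes = unique(edges$gene_id))
  metrics <- node_metrics(net)
  for (i in seq_len(nrow(metrics))) {
    expected <- if (metrics$layer[i] == "miR") {
      oracle_redundancy(edges, metrics$node_id[i], "mir_id", "gene_id")
    } else {
      oracle_redundancy(edges, metrics$node_id[i], "gene_id", "mir_id")
    }
    expect_equal(metrics$redundancy[i], expected,
                 info = paste("node", metrics$node_id[i]))
  }
}
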