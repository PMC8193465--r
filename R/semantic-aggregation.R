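#' Read an ontology DAG
#'
#' @param path Three-column TSV (`child_id`, `parent_id`, `edge_type`) with
#'   edge types `is_a` / `part_of`.
#' @return Tibble with those three columns.
#' @export
read_ontology <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1:3] <- c("child_id", "parent_id", "edge_type")
  validate_dag(tbl)
  tbl
}

validate_dag <- function(dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(all(c("child_id", "parent_id", "edge_type") %in% names(dag)))
  bad <- setdiff(unique(dag$edge_type), names(weights))
  if (length(bad) > 0) {
    stop("edge type(s) without a contribution weight: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(dag[c("child_id", "parent_id")], directed = TRUE)
  if (!igraph::is_dag(g)) stop("ontology contains a cycle", call. = FALSE)
  invisible(dag)
}

dag_terms <- function(dag) unique(c(dag$child_id, dag$parent_id))

#' Wang S-values of a term over its ancestor closure
#'
#' The semantic contribution of each ancestor t of a term A:
#' `S_A(A) = 1` and, walking up the DAG,
#' `S_A(t) = max over children t' of t within A's closure of w_e(t' -> t) * S_A(t')`,
#' where `w_e` is the contribution weight of the connecting edge type.
#'
#' @param term Term id.
#' @param dag Ontology tibble (`child_id`, `parent_id`, `edge_type`).
#' @param weights Named edge-type contribution weights, each in (0, 1).
#' @return Named numeric vector of S-values over `term` and its ancestors.
#' @export
term_svalues <- function(term, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (any(weights <= 0 | weights >= 1)) {
    stop("edge weights must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!term %in% dag_terms(dag)) stop("term not in DAG: ", term, call. = FALSE)
  validate_dag(dag, weights)

  # upward closure of `term`
  closure <- term
  frontier <- term
  repeat {
    nxt <- setdiff(dag$parent_id[dag$child_id %in% frontier], closure)
    if (length(nxt) == 0) break
    closure <- c(closure, nxt)
    frontier <- nxt
  }
  sub <- dag[dag$child_id %in% closure & dag$parent_id %in% closure, ]
  s <- setNames(rep(-Inf, length(closure)), closure)
  s[term] <- 1
  if (nrow(sub) > 0) {
    g <- igraph::graph_from_data_frame(sub[c("child_id", "parent_id")],
                                       directed = TRUE, vertices = closure)
    ord <- igraph::V(g)$name[igraph::topo_sort(g, mode = "out")]
    for (t in ord) {
      inc <- sub[sub$parent_id == t, ]
      if (nrow(inc) > 0) {
        cand <- weights[inc$edge_type] * s[inc$child_id]
        s[t] <- max(s[t], cand)
      }
    }
  }
  s[is.finite(s)]
}

#' Wang semantic similarity between two ontology terms
#'
#' `sim(A, B) = sum over shared ancestors t of (S_A(t) + S_B(t)) /
#' (SV(A) + SV(B))` with `SV(X) = sum of X's S-values`. Symmetric, in
#' `[0, 1]`, with `sim(A, A) = 1`; terms in disconnected DAG components share
#' no ancestor and score 0.
#'
#' @inheritParams term_svalues
#' @param a,b Term ids.
#' @return Similarity in `[0, 1]`.
#' @export
wang_similarity <- function(a, b, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  sa <- term_svalues(a, dag, weights)
  sb <- term_svalues(b, dag, weights)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

#' Pairwise Wang similarity matrix
#'
#' @inheritParams term_svalues
#' @param terms Character vector of term ids.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
wang_similarity_matrix <- function(terms, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(length(terms) >= 1, !anyDuplicated(terms))
  sv <- lapply(terms, term_svalues, dag = dag, weights = weights)
  n <- length(terms)
  out <- diag(1, n)
  dimnames(out) <- list(terms, terms)
  if (n > 1) {
    tot <- vapply(sv, sum, numeric(1))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shared <- intersect(names(sv[[i]]), names(sv[[j]]))
        out[i, j] <- out[j, i] <- if (length(shared) == 0) 0 else
          sum(sv[[i]][shared] + sv[[j]][shared]) / (tot[i] + tot[j])
      }
    }
  }
  out
}

#' Cluster enriched terms by semantic similarity
#'
#' Average-linkage agglomerative clustering on the distance `1 - sim`, cut
#' into `min(n_groups, n_terms)` groups. Deterministic given the input order.
#'
#' @param sim Symmetric similarity matrix with unit diagonal and term ids as
#'   dimnames.
#' @param n_groups Requested number of groups (default 10); capped at the
#'   number of terms.
#' @return Tibble with columns `term_id` and `group`.
#' @export
cluster_terms <- function(sim, n_groups = 10) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim) ||
      !isTRUE(all.equal(sim, t(sim))) ||
      !isTRUE(all.equal(unname(diag(sim)), rep(1, nrow(sim))))) {
    stop("sim must be a symmetric matrix with unit diagonal", call. = FALSE)
  }
  terms <- rownames(sim)
  n <- nrow(sim)
  k <- min(n_groups, n)
  grp <- if (n == 1) 1L else {
    hc <- hclust(as.dist(1 - sim), method = "average")
    as.integer(cutree(hc, k = k))
  }
  tibble::tibble(term_id = terms, group = grp)
}

#' Representative term of a function group
#'
#' The member with the lowest adjusted p-value; ties are broken by smaller
#' raw p-value, then by lexicographically smaller term id.
#'
#' @param members Character vector of term ids in the group.
#' @param enrichment Enrichment tibble from [enrich_neighborhood()] covering
#'   every member.
#' @return The representative term id.
#' @export
select_representative <- function(members, enrichment) {
  missing <- setdiff(members, enrichment$term_id)
  if (length(missing) > 0) {
    stop("member(s) lacking an enrichment result: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  e <- enrichment[enrichment$term_id %in% members, ]
  e <- e[order(e$adj_p_value, e$p_value, e$term_id), ]
  e$term_id[1]
}

#' Aggregate enriched terms into function groups
#'
#' Computes pairwise Wang similarity over the supplied (typically
#' significant) terms, clusters them into up to `n_groups` groups and selects
#' a representative term per group.
#'
#' @param enrichment Enrichment tibble restricted to the terms to aggregate.
#' @inheritParams term_svalues
#' @inheritParams cluster_terms
#' @return Tibble with columns `group`, `n_members`, `representative`,
#'   `representative_adj_p` and list-column `members`.
#' @export
function_groups <- function(enrichment, dag, n_groups = 10,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(nrow(enrichment) >= 1)
  sim <- wang_similarity_matrix(enrichment$term_id, dag, weights)
  cl <- cluster_terms(sim, n_groups)
  cl |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      representative = select_representative(.data$term_id, enrichment),
      members = list(.data$term_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(representative_adj_p = enrichment$adj_p_value[
      match(.data$representative, enrichment$term_id)]) |>
    dplyr::select("group", "n_members", "representative",
                  "representative_adj_p", "members") |>
    dplyr::arrange(.data$representative_adj_p, .data$representative)
}
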