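#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X hypergeometric with universe size `N`, `K` annotated
#' genes, and a query of size `n` — the over-representation p-value of an
#' observed overlap of `k` genes. Evaluated via the survival function of the
#' hypergeometric distribution (log-space internally).
#'
#' @param N Universe size.
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param k Observed overlap.
#' @return Probability in `[0, 1]`; `k = 0` gives 1.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    stop("require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)", call. = FALSE)
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sorted p-values are scaled by
#' m/i, made monotone from the largest down, capped at 1 and returned in the
#' original order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise >= the input and <= 1.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Read a term-to-gene annotation table
#'
#' @param path Two-column TSV (`term_id`, `gene_id`).
#' @return Tibble with columns `term_id` and `gene_id`.
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1:2] <- c("term_id", "gene_id")
  dplyr::distinct(tbl)
}

#' Over-representation analysis of a gene neighbourhood
#'
#' Hypergeometric test of every annotation term against a query gene set,
#' with multiple-testing adjustment across all tested terms. Term sizes are
#' computed after intersecting annotations with the universe; terms with no
#' universe gene are skipped (not assigned p = 1) and excluded from the
#' adjustment family. Query genes outside the universe are dropped with a
#' warning.
#'
#' @param query Character vector of query gene ids (e.g. a commodore
#'   neighbourhood).
#' @param universe Character vector of background gene ids.
#' @param annotations Tibble (`term_id`, `gene_id`) mapping terms to genes.
#' @param alpha Significance threshold on the adjusted p-value (default 1e-3).
#' @param method Adjustment method, `"BH"` (default) or `"bonferroni"`.
#' @param term_names Optional tibble (`term_id`, `name`) of readable names.
#' @return Tibble with one row per tested term: `term_id`, `universe_size`,
#'   `term_size`, `query_size`, `overlap`, `p_value`, `adj_p_value`,
#'   `significant`, ordered by increasing p-value.
#' @export
enrich_neighborhood <- function(query, universe, annotations, alpha = 1e-3,
                                method = c("BH", "bonferroni"),
                                term_names = NULL) {
  method <- match.arg(method)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe were dropped",
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) stop("empty query after intersection with universe",
                               call. = FALSE)

  ann <- annotations[annotations$gene_id %in% universe, c("term_id", "gene_id")]
  ann <- dplyr::distinct(ann)
  if (nrow(ann) == 0) stop("no annotation overlaps the universe", call. = FALSE)

  N <- length(universe)
  n <- length(query)
  per_term <- ann |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(term_size = dplyr::n(),
                     overlap = sum(.data$gene_id %in% query),
                     .groups = "drop")
  p <- phyper(per_term$overlap - 1, per_term$term_size,
              N - per_term$term_size, n, lower.tail = FALSE)
  adj <- if (method == "BH") bh_adjust(p) else pmin(1, p * length(p))

  out <- tibble::tibble(
    term_id = per_term$term_id,
    universe_size = N,
    term_size = per_term$term_size,
    query_size = n,
    overlap = per_term$overlap,
    p_value = p,
    adj_p_value = adj,
    significant = adj <= alpha
  )
  if (!is.null(term_names)) {
    out <- dplyr::left_join(out, term_names, by = "term_id")
  }
  dplyr::arrange(out, .data$p_value, .data$term_id)
}
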