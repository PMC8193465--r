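#' Read an expression table
#'
#' Reads a tab-separated expression table (rows are transcripts, columns are
#' samples, first column holds transcript identifiers) into a tidy expression
#' tibble. Gene layers typically carry FPKM values, miR layers
#' reads-per-million-miRNA-mapped (RPMMM); both are consumed as-is.
#'
#' @param path Path to a TSV file with a header row of sample ids.
#' @param layer Expression layer, `"gene"` or `"miR"`.
#' @return A tibble with a `transcript_id` column followed by one numeric
#'   column per sample, carrying a `"layer"` attribute.
#' @export
read_expression <- function(path, layer = c("gene", "miR")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) {
    stop("expression table not found: ", path, call. = FALSE)
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2) {
    stop("malformed expression table (need transcript id column plus >= 1 sample): ",
         path, call. = FALSE)
  }
  names(tbl)[1] <- "transcript_id"
  tbl$transcript_id <- as.character(tbl$transcript_id)
  as_expression(tbl, layer = layer)
}

#' Coerce a data frame to a validated expression tibble
#'
#' @param x Data frame whose first column is `transcript_id` and whose
#'   remaining columns are numeric sample values.
#' @param layer Expression layer, `"gene"` or `"miR"`.
#' @return The validated expression tibble with a `"layer"` attribute.
#' @export
as_expression <- function(x, layer = c("gene", "miR")) {
  layer <- match.arg(layer)
  x <- tibble::as_tibble(x)
  stopifnot("transcript_id" %in% names(x)[1])
  dup <- x$transcript_id[duplicated(x$transcript_id)]
  if (length(dup) > 0) {
    stop("duplicate transcript id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  samp <- setdiff(names(x), "transcript_id")
  if (anyDuplicated(samp)) {
    stop("duplicate sample id(s) in header", call. = FALSE)
  }
  vals <- as.matrix(x[samp])
  if (!is.numeric(vals)) {
    stop("non-numeric expression values", call. = FALSE)
  }
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("negative expression values are not allowed", call. = FALSE)
  }
  attr(x, "layer") <- layer
  x
}

#' Write an expression tibble to TSV
#'
#' @param x Expression tibble (see [as_expression()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read or write a sample-to-subtype assignment
#'
#' The assignment is a two-column TSV (`sample_id`, `subtype`); every sample
#' maps to exactly one subtype label.
#'
#' @param path File path.
#' @return A tibble with columns `sample_id` and `subtype`.
#' @export
read_subtype_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1:2] <- c("sample_id", "subtype")
  if (anyDuplicated(tbl$sample_id)) {
    stop("sample(s) assigned to more than one subtype", call. = FALSE)
  }
  tbl
}

#' @rdname read_subtype_map
#' @param x Subtype assignment tibble.
#' @export
write_subtype_map <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Subset an expression tibble to the samples of one subtype
#'
#' Pure column selection: samples carrying the requested label are kept in
#' their original order. Samples present in the expression table but absent
#' from the assignment are dropped with a warning. Mutual information over
#' equal-frequency bins needs at least two bins of two samples, so fewer than
#' four matching samples is an error.
#'
#' @param expr Expression tibble.
#' @param assign Subtype assignment tibble (`sample_id`, `subtype`).
#' @param subtype Subtype label to keep.
#' @return Expression tibble restricted to the matching sample columns.
#' @export
split_by_subtype <- function(expr, assign, subtype) {
  samp <- setdiff(names(expr), "transcript_id")
  unassigned <- setdiff(samp, assign$sample_id)
  if (length(unassigned) > 0) {
    warning(length(unassigned), " sample(s) absent from the subtype assignment were dropped",
            call. = FALSE)
    samp <- setdiff(samp, unassigned)
  }
  if (!subtype %in% assign$subtype) {
    stop("unknown subtype label: ", subtype, call. = FALSE)
  }
  keep <- samp[samp %in% assign$sample_id[assign$subtype == subtype]]
  if (length(keep) < 4) {
    stop("subtype '", subtype, "' has ", length(keep),
         " sample(s); at least 4 are required", call. = FALSE)
  }
  out <- expr[c("transcript_id", keep)]
  attr(out, "layer") <- attr(expr, "layer")
  out
}

#' Drop transcripts with zero variance across samples
#'
#' A constant expression vector cannot be split into two or more
#' equal-frequency bins, so such transcripts are removed before mutual
#' information scoring. Dropped ids are reported via a message.
#'
#' @param expr Expression tibble.
#' @return Expression tibble without zero-variance transcripts.
#' @export
drop_invariant_transcripts <- function(expr) {
  vals <- expression_values(expr)
  const <- apply(vals, 1, function(r) min(r) == max(r))
  if (any(const)) {
    message("dropping ", sum(const), " zero-variance transcript(s): ",
            paste(head(expr$transcript_id[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "")
    out <- expr[!const, ]
    attr(out, "layer") <- attr(expr, "layer")
    return(out)
  }
  expr
}

# numeric value matrix (transcripts x samples) of an expression tibble
expression_values <- function(expr) {
  samp <- setdiff(names(expr), "transcript_id")
  m <- as.matrix(expr[samp])
  rownames(m) <- expr$transcript_id
  m
}
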