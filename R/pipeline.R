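#' Pipeline configuration
#'
#' Collects every tunable of the per-subtype workflow. Defaults are the
#' method's canonical parameters: edge quantile 0.9999, commodore thresholds
#' k >= 100 and rc <= 0.5, enrichment significance at adjusted p <= 1e-3,
#' and ten function groups.
#'
#' Inputs may be given either as in-memory objects (expression tibbles,
#' ontology tibbles) or as file paths, or omitted entirely in favour of
#' synthetic mode.
#'
#' @param gene,mir Expression tibbles or TSV paths.
#' @param subtypes Subtype assignment tibble or TSV path.
#' @param dag Ontology tibble or TSV path (optional; enrichment and
#'   aggregation are skipped without it).
#' @param annotations Term-to-gene tibble or TSV path (optional).
#' @param term_names Optional tibble (`term_id`, `name`).
#' @param synthetic Optional list of generator parameters (`n_samples`,
#'   `n_genes`, `n_mirs`, optionally `planted`, `n_terms`); when given, all
#'   inputs are simulated from `seed`.
#' @param quantile Edge-retention upper quantile (default 0.9999).
#' @param n_bins MI bins; `NULL` means `floor(sqrt(n_samples))`.
#' @param k_min,rc_max Commodore thresholds (defaults 100 and 0.5).
#' @param alpha Enrichment significance threshold (default 1e-3).
#' @param n_groups Function groups per commodore (default 10).
#' @param seed Integer seed governing all randomness.
#' @param out_dir Output directory for the report bundle (`NULL`: no files).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(gene = NULL, mir = NULL, subtypes = NULL,
                            dag = NULL, annotations = NULL, term_names = NULL,
                            synthetic = NULL,
                            quantile = 0.9999, n_bins = NULL,
                            k_min = 100, rc_max = 0.5, alpha = 1e-3,
                            n_groups = 10, seed = 1, out_dir = NULL) {
  if (is.null(synthetic) && (is.null(gene) || is.null(mir) || is.null(subtypes))) {
    stop("either supply gene/mir/subtypes inputs or a synthetic specification",
         call. = FALSE)
  }
  structure(
    list(gene = gene, mir = mir, subtypes = subtypes, dag = dag,
         annotations = annotations, term_names = term_names,
         synthetic = synthetic, quantile = quantile, n_bins = n_bins,
         k_min = k_min, rc_max = rc_max, alpha = alpha,
         n_groups = n_groups, seed = seed, out_dir = out_dir),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE)
  })
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full commodore discovery workflow
#'
#' Per subtype: subset samples, drop invariant transcripts, score all
#' miR-gene pairs by mutual information, threshold at the global quantile,
#' compute node metrics and the network summary, classify commodores and,
#' when an ontology is supplied, enrich each commodore neighbourhood and
#' aggregate the significant terms into function groups. A Jaccard matrix
#' over all commodore neighbourhoods and a run manifest complete the bundle.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages?
#' @return Invisibly, a named list: `summaries`, `metrics`, `commodores`,
#'   `enrichment`, `groups`, `jaccard`, `networks`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[cdremir] ", ...)

  onto <- NULL
  if (!is.null(config$synthetic)) {
    say("stage simulate: generating synthetic inputs (seed ", config$seed, ")")
    sim <- with_stage("simulate", {
      sp <- config$synthetic
      planted <- sp$planted %||% example_planted_structures()
      simulate_expression(sp$n_samples, sp$n_genes, sp$n_mirs,
                          planted, seed = config$seed)
    })
    gene <- sim$gene; mir <- sim$mir; subtypes <- sim$subtypes
    n_terms <- config$synthetic$n_terms %||% 150
    onto <- with_stage("simulate", simulate_ontology(
      n_terms, sim$planted, gene$transcript_id, seed = config$seed + 1))
    dag <- onto$dag; annotations <- onto$annotations; term_names <- onto$term_names
  } else {
    say("stage load: reading inputs")
    gene <- with_stage("load", resolve_input(config$gene,
                                             function(p) read_expression(p, "gene")))
    mir <- with_stage("load", resolve_input(config$mir,
                                            function(p) read_expression(p, "miR")))
    subtypes <- with_stage("load", resolve_input(config$subtypes, read_subtype_map))
    dag <- with_stage("load", resolve_input(config$dag, read_ontology))
    annotations <- with_stage("load", resolve_input(config$annotations, read_annotations))
    term_names <- config$term_names
  }

  labels <- sort(unique(subtypes$subtype))
  res <- list(summaries = list(), metrics = list(), commodores = list(),
              enrichment = list(), groups = list(), networks = list())

  for (sub in labels) {
    say("stage network [", sub, "]: MI scoring and thresholding")
    net <- with_stage(paste0("network/", sub), {
      g <- drop_invariant_transcripts(split_by_subtype(gene, subtypes, sub))
      m <- drop_invariant_transcripts(split_by_subtype(mir, subtypes, sub))
      threshold_network(mi_scores(m, g, n_bins = config$n_bins),
                        quantile = config$quantile)
    })
    res$networks[[sub]] <- net

    say("stage metrics [", sub, "]")
    metrics <- with_stage(paste0("metrics/", sub), node_metrics(net))
    res$metrics[[sub]] <- dplyr::mutate(metrics, subtype = sub, .before = 1)
    res$summaries[[sub]] <- dplyr::mutate(network_summary(net), subtype = sub,
                                          .before = 1)

    say("stage commodore [", sub, "]")
    cds <- with_stage(paste0("commodore/", sub), {
      cc <- classify_commodores(metrics, k_min = config$k_min,
                                rc_max = config$rc_max)
      tibble::tibble(
        subtype = rep(sub, nrow(cc)), mir_id = cc$mir_id,
        degree = cc$degree, redundancy = cc$redundancy,
        neighborhood = purrr::map(cc$mir_id, ~ mir_neighborhood(net, .x))
      )
    })
    res$commodores[[sub]] <- cds

    if (!is.null(dag) && !is.null(annotations) && nrow(cds) > 0) {
      universe <- with_stage(paste0("enrich/", sub), {
        expressed <- drop_invariant_transcripts(
          split_by_subtype(gene, subtypes, sub))$transcript_id
        intersect(expressed, unique(annotations$gene_id))
      })
      for (i in seq_len(nrow(cds))) {
        key <- paste(sub, cds$mir_id[i], sep = ":")
        say("stage enrich [", key, "]")
        enr <- with_stage(paste0("enrich/", key), enrich_neighborhood(
          cds$neighborhood[[i]], universe, annotations,
          alpha = config$alpha, term_names = term_names))
        res$enrichment[[key]] <- dplyr::mutate(
          enr, subtype = sub, mir_id = cds$mir_id[i], .before = 1)
        sig <- enr[enr$significant, ]
        if (nrow(sig) > 0) {
          say("stage aggregate [", key, "]: ", nrow(sig), " enriched term(s)")
          grp <- with_stage(paste0("aggregate/", key),
                            function_groups(sig, dag, n_groups = config$n_groups))
          res$groups[[key]] <- dplyr::mutate(
            grp, subtype = sub, mir_id = cds$mir_id[i], .before = 1)
        }
      }
    }
  }

  all_cds <- dplyr::bind_rows(res$commodores)
  res$jaccard <- if (nrow(all_cds) > 0) neighborhood_jaccard(all_cds) else NULL
  res$summaries <- dplyr::bind_rows(res$summaries)
  res$metrics <- dplyr::bind_rows(res$metrics)
  res$commodores <- all_cds
  res$enrichment <- dplyr::bind_rows(res$enrichment)
  res$groups <- dplyr::bind_rows(res$groups)
  res$manifest <- list(
    parameters = list(quantile = config$quantile, n_bins = config$n_bins,
                      k_min = config$k_min, rc_max = config$rc_max,
                      alpha = config$alpha, n_groups = config$n_groups),
    seed = config$seed,
    synthetic = config$synthetic[c("n_samples", "n_genes", "n_mirs", "n_terms")],
    subtypes = labels
  )

  if (!is.null(config$out_dir)) {
    say("stage export: writing report bundle to ", config$out_dir)
    with_stage("export", write_report_bundle(res, config$out_dir))
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report bundle
#'
#' One TSV per result table, a GraphML and edge-list file per subtype
#' network, the commodore neighbourhood gene lists, the Jaccard matrix and a
#' YAML manifest recording all parameters and the seed. Output files are
#' byte-stable for a fixed seed.
#'
#' @param res Result list from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_tsv(res$summaries, p("network_summary.tsv"), progress = FALSE)
  readr::write_tsv(res$metrics, p("node_metrics.tsv"), progress = FALSE)
  readr::write_tsv(dplyr::select(res$commodores, -"neighborhood"),
                   p("commodores.tsv"), progress = FALSE)
  if (nrow(res$enrichment) > 0) {
    readr::write_tsv(res$enrichment, p("enrichment.tsv"), progress = FALSE)
  }
  if (nrow(res$groups) > 0) {
    readr::write_tsv(
      dplyr::mutate(res$groups,
                    members = purrr::map_chr(.data$members, paste, collapse = ",")),
      p("function_groups.tsv"), progress = FALSE)
  }
  for (sub in names(res$networks)) {
    write_edge_list(res$networks[[sub]], p(paste0("edges_", sub, ".tsv")))
    write_graphml(res$networks[[sub]], p(paste0("network_", sub, ".graphml")))
  }
  if (nrow(res$commodores) > 0) {
    dir.create(p("neighborhoods"), showWarnings = FALSE)
    for (i in seq_len(nrow(res$commodores))) {
      writeLines(res$commodores$neighborhood[[i]],
                 p("neighborhoods",
                   paste0(res$commodores$subtype[i], "_",
                          res$commodores$mir_id[i], ".txt")))
    }
  }
  if (!is.null(res$jaccard)) {
    jm <- tibble::as_tibble(res$jaccard, rownames = "neighborhood")
    readr::write_tsv(jm, p("neighborhood_jaccard.tsv"), progress = FALSE)
  }
  writeLines(yaml::as.yaml(res$manifest), p("manifest.yaml"))
  invisible(out_dir)
}

#' Literature-query strings for commodore function groups
#'
#' Builds the query strings of the form "miR + representative term" that a
#' literature search would use, one per function group, without contacting
#' any external service.
#'
#' @param groups Function-group tibble from [run_pipeline()] (columns
#'   `subtype`, `mir_id`, `representative`).
#' @param term_names Optional tibble (`term_id`, `name`) used to spell the
#'   representative term out.
#' @return Tibble with columns `subtype`, `mir_id`, `representative`, `query`.
#' @export
pubmed_query_strings <- function(groups, term_names = NULL) {
  rep_label <- groups$representative
  if (!is.null(term_names)) {
    nm <- term_names$name[match(groups$representative, term_names$term_id)]
    rep_label <- ifelse(is.na(nm), rep_label, nm)
  }
  tibble::tibble(
    subtype = groups$subtype,
    mir_id = groups$mir_id,
    representative = groups$representative,
    query = paste(groups$mir_id, "+", rep_label)
  )
}
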