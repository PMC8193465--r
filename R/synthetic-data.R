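#' Planted network structure for the synthetic-data generator
#'
#' Describes the ground truth planted into one synthetic phenotype: driver
#' ("commodore") miRs with disjoint private target sets, and redundant hub
#' groups — several miRs sharing one common target set, which makes every
#' member fully redundant (rc = 1) and therefore rejected by the commodore
#' filter.
#'
#' @param commodore_mirs Character vector of planted driver miR ids.
#' @param commodore_targets List (parallel to `commodore_mirs`) of target gene
#'   id vectors; pairwise disjoint across drivers.
#' @param redundant_groups List of character vectors of miR ids; every group
#'   has >= 2 members.
#' @param redundant_targets List (parallel to `redundant_groups`) of the gene
#'   set shared by all members of each group.
#' @param driver_strength Latent-factor loading in `[0, 1]`; 0 means all
#'   transcripts are mutually independent.
#' @param noise_meanlog,noise_sdlog Location and scale of the log-normal
#'   background expression.
#' @return An object of class `planted_structure`.
#' @export
planted_structure <- function(commodore_mirs = character(),
                              commodore_targets = list(),
                              redundant_groups = list(),
                              redundant_targets = list(),
                              driver_strength = 0.9,
                              noise_meanlog = 0, noise_sdlog = 1) {
  if (!is.numeric(driver_strength) || driver_strength < 0 || driver_strength > 1) {
    stop("driver_strength must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(commodore_mirs) == length(commodore_targets),
            length(redundant_groups) == length(redundant_targets))
  all_targets <- unlist(commodore_targets)
  if (anyDuplicated(all_targets)) {
    stop("commodore target sets must be pairwise disjoint", call. = FALSE)
  }
  if (any(vapply(redundant_groups, length, integer(1)) < 2)) {
    stop("every redundant hub group needs >= 2 miRs", call. = FALSE)
  }
  structure(
    list(commodore_mirs = commodore_mirs,
         commodore_targets = commodore_targets,
         redundant_groups = redundant_groups,
         redundant_targets = redundant_targets,
         driver_strength = driver_strength,
         noise_meanlog = noise_meanlog,
         noise_sdlog = noise_sdlog),
    class = "planted_structure"
  )
}

synthetic_gene_ids <- function(n) sprintf("gene%05d", seq_len(n))
synthetic_mir_ids <- function(n) sprintf("mir%04d", seq_len(n))

#' Standard planted structures for a multi-phenotype simulation
#'
#' Builds one [planted_structure()] per synthetic subtype in the generator's
#' id scheme: each active subtype gets one driver miR with `n_targets`
#' private target genes and one redundant hub group of `group_size` miRs
#' sharing `group_targets` genes; all planted ids are disjoint across
#' subtypes. Inactive subtypes are pure background noise.
#'
#' @param n_subtypes Number of synthetic subtypes.
#' @param active Logical vector: which subtypes carry planted structure.
#' @param n_targets Driver target-set size (default 120).
#' @param group_size Redundant group size (default 3).
#' @param group_targets Shared target-set size of each group (default 110).
#' @param driver_strength Latent-factor loading (default 0.9).
#' @param noise_meanlog,noise_sdlog Background log-normal parameters.
#' @return Named list of `planted_structure` objects
#'   (`subtype1`, `subtype2`, ...).
#' @export
example_planted_structures <- function(n_subtypes = 4,
                                       active = rep(TRUE, n_subtypes),
                                       n_targets = 120, group_size = 3,
                                       group_targets = 110,
                                       driver_strength = 0.9,
                                       noise_meanlog = 0, noise_sdlog = 1) {
  stopifnot(length(active) == n_subtypes)
  block <- n_targets + group_targets
  out <- vector("list", n_subtypes)
  names(out) <- paste0("subtype", seq_len(n_subtypes))
  for (s in seq_len(n_subtypes)) {
    if (!active[s]) {
      out[[s]] <- planted_structure(driver_strength = driver_strength,
                                    noise_meanlog = noise_meanlog,
                                    noise_sdlog = noise_sdlog)
      next
    }
    driver <- synthetic_mir_ids(s)[s]
    grp <- synthetic_mir_ids(n_subtypes + s * group_size)[
      n_subtypes + (s - 1) * group_size + seq_len(group_size)]
    genes <- synthetic_gene_ids((s - 1) * block + block)
    tgt <- genes[(s - 1) * block + seq_len(n_targets)]
    shr <- genes[(s - 1) * block + n_targets + seq_len(group_targets)]
    out[[s]] <- planted_structure(
      commodore_mirs = driver, commodore_targets = list(tgt),
      redundant_groups = list(grp), redundant_targets = list(shr),
      driver_strength = driver_strength,
      noise_meanlog = noise_meanlog, noise_sdlog = noise_sdlog
    )
  }
  out
}

#' Simulate paired miR / gene expression with planted structure
#'
#' Generates two FPKM-like expression layers over round-robin subtype labels.
#' All transcripts start as independent log-normal noise; within each
#' subtype's samples, every planted driver (and each redundant hub group)
#' shares one latent standard-normal factor with its targets:
#' on the log scale `z = strength * factor + (1 - strength) * noise`, then
#' `expr = exp(meanlog + sdlog * z)`. The monotone link guarantees an MI
#' signal under equal-frequency binning; `strength = 0` recovers full mutual
#' independence. Fully reproducible from `seed`.
#'
#' @param n_samples Total number of samples (split round-robin over
#'   subtypes); every subtype needs >= 4.
#' @param n_genes,n_mirs Layer sizes; must cover all planted ids.
#' @param planted A [planted_structure()] (one subtype, labelled
#'   `"subtype1"`) or a named list of them, one per subtype.
#' @param seed Integer seed for all randomness.
#' @return List with elements `gene` and `mir` (expression tibbles),
#'   `subtypes` (sample-to-subtype tibble) and `planted`.
#' @export
simulate_expression <- function(n_samples, n_genes, n_mirs, planted, seed = 1) {
  if (n_samples < 4 || n_genes < 1 || n_mirs < 1) {
    stop("dimensions must be positive (and n_samples >= 4)", call. = FALSE)
  }
  if (inherits(planted, "planted_structure")) planted <- list(subtype1 = planted)
  stopifnot(all(vapply(planted, inherits, logical(1), "planted_structure")),
            !is.null(names(planted)))

  gene_ids <- synthetic_gene_ids(n_genes)
  mir_ids <- synthetic_mir_ids(n_mirs)
  sample_ids <- sprintf("sample%04d", seq_len(n_samples))
  subtype_of <- names(planted)[(seq_len(n_samples) - 1) %% length(planted) + 1]

  for (ps in planted) {
    bad_m <- setdiff(c(ps$commodore_mirs, unlist(ps$redundant_groups)), mir_ids)
    bad_g <- setdiff(unlist(c(ps$commodore_targets, ps$redundant_targets)), gene_ids)
    if (length(bad_m) > 0 || length(bad_g) > 0) {
      stop("planted ids outside the simulated universe: ",
           paste(c(bad_m, bad_g), collapse = ", "), call. = FALSE)
    }
  }
  if (any(table(subtype_of) < 4)) {
    stop("every subtype needs >= 4 samples", call. = FALSE)
  }

  withr::with_seed(seed, {
    zg <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(gene_ids, sample_ids))
    zm <- matrix(rnorm(n_mirs * n_samples), n_mirs, n_samples,
                 dimnames = list(mir_ids, sample_ids))
    for (sub in names(planted)) {
      ps <- planted[[sub]]
      cols <- which(subtype_of == sub)
      s <- ps$driver_strength
      blend <- function(rows_m, rows_g) {
        f <- rnorm(length(cols))
        if (length(rows_m) > 0) {
          zm[rows_m, cols] <<- s * matrix(f, length(rows_m), length(cols),
                                          byrow = TRUE) +
            (1 - s) * zm[rows_m, cols, drop = FALSE]
        }
        if (length(rows_g) > 0) {
          zg[rows_g, cols] <<- s * matrix(f, length(rows_g), length(cols),
                                          byrow = TRUE) +
            (1 - s) * zg[rows_g, cols, drop = FALSE]
        }
      }
      for (i in seq_along(ps$commodore_mirs)) {
        blend(match(ps$commodore_mirs[i], mir_ids),
              match(ps$commodore_targets[[i]], gene_ids))
      }
      for (i in seq_along(ps$redundant_groups)) {
        blend(match(ps$redundant_groups[[i]], mir_ids),
              match(ps$redundant_targets[[i]], gene_ids))
      }
    }
    ml <- planted[[1]]$noise_meanlog
    sl <- planted[[1]]$noise_sdlog
    gexpr <- exp(ml + sl * zg)
    mexpr <- exp(ml + sl * zm)

    list(
      gene = as_expression(
        tibble::as_tibble(cbind(tibble::tibble(transcript_id = gene_ids),
                                as.data.frame(gexpr))), layer = "gene"),
      mir = as_expression(
        tibble::as_tibble(cbind(tibble::tibble(transcript_id = mir_ids),
                                as.data.frame(mexpr))), layer = "miR"),
      subtypes = tibble::tibble(sample_id = sample_ids, subtype = subtype_of),
      planted = planted
    )
  })
}

#' Simulate a toy ontology annotating the planted neighbourhoods
#'
#' Builds a single-rooted acyclic ontology of `n_terms` terms in which one
#' designated "true" term per planted driver annotates exactly that driver's
#' target gene set; all remaining terms annotate random gene subsets of the
#' universe. Reproducible from `seed`.
#'
#' @param n_terms Number of terms (>= 2 and >= number of drivers + 1).
#' @param planted A [planted_structure()] or named list of them.
#' @param gene_ids Gene universe to annotate.
#' @param seed Integer seed.
#' @return List with `dag` (child/parent/edge-type tibble), `annotations`
#'   (`term_id`, `gene_id`), `term_names` and `true_terms` (term to planted
#'   driver mapping).
#' @export
simulate_ontology <- function(n_terms, planted, gene_ids, seed = 1) {
  if (n_terms < 2) stop("n_terms must be >= 2", call. = FALSE)
  if (inherits(planted, "planted_structure")) planted <- list(subtype1 = planted)
  drivers <- purrr::imap_dfr(planted, function(ps, sub) {
    tibble::tibble(subtype = sub, mir_id = ps$commodore_mirs,
                   targets = ps$commodore_targets)
  })
  if (n_terms < nrow(drivers) + 1) {
    stop("n_terms too small for ", nrow(drivers), " planted driver(s)", call. = FALSE)
  }
  term_ids <- sprintf("TERM%04d", seq_len(n_terms))

  withr::with_seed(seed, {
    dag <- purrr::map_dfr(2:n_terms, function(i) {
      n_par <- if (i == 2) 1L else sample(1:2, 1, prob = c(0.7, 0.3))
      parents <- sample(term_ids[seq_len(i - 1)], n_par)
      tibble::tibble(
        child_id = term_ids[i],
        parent_id = parents,
        edge_type = if (i == 2) "is_a" else
          sample(c("is_a", "part_of"), n_par, replace = TRUE, prob = c(0.7, 0.3))
      )
    })

    true_terms <- tibble::tibble(
      term_id = term_ids[1 + seq_len(nrow(drivers))],
      subtype = drivers$subtype,
      mir_id = drivers$mir_id
    )
    ann_true <- purrr::map2_dfr(true_terms$term_id, drivers$targets,
                                ~ tibble::tibble(term_id = .x, gene_id = .y))
    other <- setdiff(term_ids, true_terms$term_id)
    max_size <- max(20L, min(200L, floor(length(gene_ids) / 10)))
    ann_other <- purrr::map_dfr(other, function(t) {
      size <- sample(seq(20L, max_size), 1)
      size <- min(size, length(gene_ids))
      tibble::tibble(term_id = t, gene_id = sample(gene_ids, size))
    })
    list(
      dag = dag,
      annotations = dplyr::bind_rows(ann_true, ann_other),
      term_names = tibble::tibble(
        term_id = term_ids,
        name = ifelse(term_ids %in% true_terms$term_id,
                      paste0("planted process ", term_ids),
                      paste0("synthetic process ", term_ids))
      ),
      true_terms = true_terms
    )
  })
}

#' Write a toy ontology to disk
#'
#' @param onto List from [simulate_ontology()].
#' @param dag_path,annotation_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_ontology <- function(onto, dag_path, annotation_path) {
  readr::write_tsv(onto$dag, dag_path, progress = FALSE)
  readr::write_tsv(onto$annotations, annotation_path, progress = FALSE)
  invisible(c(dag_path, annotation_path))
}
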