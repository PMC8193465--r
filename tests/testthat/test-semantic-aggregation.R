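chain_dag <- tibble::tibble(child_id = "A", parent_id = "R", edge_type = "is_a")

sibling_dag <- tibble::tibble(
  child_id = c("A", "B"), parent_id = c("R", "R"), edge_type = c("is_a", "is_a")
)

diamond_dag <- tibble::tibble(
  child_id  = c("A", "A", "P1", "P2"),
  parent_id = c("P1", "P2", "R", "R"),
  edge_type = c("is_a", "part_of", "part_of", "is_a")
)

test_that("S-values follow the max-over-paths semantics", {
  # a root term contributes only itself
  expect_equal(term_svalues("R", chain_dag), c(R = 1))
  # single is_a edge: ancestor scaled by 0.8
  expect_equal(term_svalues("A", chain_dag), c(A = 1, R = 0.8))
  # diamond with mixed types: root gets the best of 0.8*0.6 and 0.6*0.8
  s <- term_svalues("A", diamond_dag)
  expect_equal(s[["A"]], 1)
  expect_equal(s[["P1"]], 0.8)
  expect_equal(s[["P2"]], 0.6)
  expect_equal(s[["R"]], 0.48)
  expect_error(term_svalues("missing", chain_dag), "not in DAG")
})

test_that("S-values equal the exhaustive path-product oracle on small DAGs", {
  set.seed(13)
  for (i in 1:60) {
    dag <- random_dag(sample(3:7, 1))
    for (term in unique(c(dag$child_id, dag$parent_id))) {
      got <- term_svalues(term, dag)
      want <- oracle_svalues(term, dag)
      expect_equal(got[order(names(got))], want[order(names(want))],
                   tolerance = 1e-12)
    }
  }
})

test_that("Wang similarity matches the hand-evaluated sibling DAG", {
  # SV(A) = SV(B) = 1 + 0.8; shared ancestor {R} contributes 0.8 + 0.8
  expect_equal(wang_similarity("A", "B", sibling_dag), 1.6 / 3.6)
  expect_equal(wang_similarity("A", "B", sibling_dag), 4 / 9)
  expect_equal(wang_similarity("A", "A", sibling_dag), 1)
})

test_that("terms in disconnected components have zero similarity", {
  dag <- tibble::tibble(child_id = c("A", "B"), parent_id = c("R1", "R2"),
                        edge_type = "is_a")
  expect_equal(wang_similarity("A", "B", dag), 0)
})

test_that("similarity is symmetric, unit-diagonal and bounded on random DAGs", {
  set.seed(29)
  for (i in 1:15) {
    dag <- random_dag(sample(4:9, 1))
    terms <- unique(c(dag$child_id, dag$parent_id))
    sim <- wang_similarity_matrix(terms, dag)
    expect_equal(sim, t(sim))
    expect_equal(unname(diag(sim)), rep(1, length(terms)))
    expect_true(all(sim >= 0 & sim <= 1))
    # matrix agrees with the pairwise function
    a <- sample(terms, 1); b <- sample(terms, 1)
    expect_equal(sim[a, b], wang_similarity(a, b, dag))
  }
})

test_that("cyclic ontologies and unknown edge types are rejected", {
  cyc <- tibble::tibble(child_id = c("A", "B"), parent_id = c("B", "A"),
                        edge_type = "is_a")
  expect_error(term_svalues("A", cyc), "cycle")
  odd <- tibble::tibble(child_id = "A", parent_id = "R", edge_type = "regulates")
  expect_error(term_svalues("A", odd), "weight")
})

test_that("clustering caps the group count and partitions the terms", {
  one <- matrix(1, 1, 1, dimnames = list("A", "A"))
  expect_equal(cluster_terms(one, 10), tibble::tibble(term_id = "A", group = 1L))

  # more groups requested than terms: all singletons
  set.seed(5)
  dag <- random_dag(7)
  terms <- unique(c(dag$child_id, dag$parent_id))
  sim <- wang_similarity_matrix(terms, dag)
  cl <- cluster_terms(sim, n_groups = 10)
  expect_equal(nrow(cl), length(terms))
  expect_equal(dplyr::n_distinct(cl$group), length(terms))

  expect_error(cluster_terms(matrix(c(1, 0.5, 0.4, 1), 2), 2), "symmetric")
})

test_that("two well-separated similarity blocks are recovered as two groups", {
  blocks <- diag(1, 6)
  blocks[1:3, 1:3] <- 0.9; blocks[4:6, 4:6] <- 0.85
  diag(blocks) <- 1
  dimnames(blocks) <- list(paste0("t", 1:6), paste0("t", 1:6))
  cl <- cluster_terms(blocks, n_groups = 2)
  expect_equal(dplyr::n_distinct(cl$group), 2L)
  expect_equal(dplyr::n_distinct(cl$group[1:3]), 1L)
  expect_equal(dplyr::n_distinct(cl$group[4:6]), 1L)

  # against the exhaustive best 2-partition by average between-block similarity
  parts <- utils::combn(1:6, 3, simplify = FALSE)
  cost <- vapply(parts, function(p) mean(blocks[p, setdiff(1:6, p)]), numeric(1))
  best <- parts[[which.min(cost)]]
  expect_setequal(paste0("t", best), cl$term_id[cl$group == cl$group[best[1]]])
})

test_that("representatives minimise adjusted then raw p with lexicographic ties", {
  enr <- tibble::tibble(
    term_id = c("tA", "tB", "tC", "tD"),
    p_value = c(0.001, 0.0005, 0.0005, 0.01),
    adj_p_value = c(0.01, 0.001, 0.001, 0.01)
  )
  expect_equal(select_representative("tD", enr), "tD")
  expect_equal(select_representative(c("tA", "tB"), enr), "tB")
  # exact tie on both p-values: smaller id wins
  expect_equal(select_representative(c("tC", "tB"), enr), "tB")
  expect_error(select_representative(c("tA", "tZ"), enr), "tZ")
})

test_that("function groups partition the enriched terms with representatives", {
  set.seed(61)
  dag <- random_dag(9)
  terms <- unique(c(dag$child_id, dag$parent_id))
  enr <- tibble::tibble(term_id = terms,
                        p_value = runif(length(terms), 0, 1e-3))
  enr$adj_p_value <- bh_adjust(enr$p_value)
  fg <- function_groups(enr, dag, n_groups = 4)
  expect_lte(nrow(fg), 4)
  expect_setequal(unlist(fg$members), terms)
  expect_equal(sum(fg$n_members), length(terms))
  for (i in seq_len(nrow(fg))) {
    expect_true(fg$representative[i] %in% fg$members[[i]])
    expect_equal(fg$representative_adj_p[i],
                 min(enr$adj_p_value[enr$term_id %in% fg$members[[i]]]))
  }
})
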