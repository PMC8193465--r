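k22 <- function() {
  bipartite_network(tidyr::expand_grid(mir_id = c("m1", "m2"),
                                       gene_id = c("g1", "g2")))
}

test_that("redundancy coefficient matches hand-worked small graphs", {
  net <- k22()
  # either miR of K_{2,2}: the other miR covers its single neighbour pair
  expect_equal(redundancy_coefficient(net, "m1"), 1)
  expect_equal(redundancy_coefficient(net, "g2"), 1)

  # a miR whose neighbour pair has no covering node is fully non-redundant
  lone <- bipartite_network(tibble::tibble(mir_id = c("m1", "m1"),
                                           gene_id = c("g1", "g2")))
  expect_equal(redundancy_coefficient(lone, "m1"), 0)

  # degree < 2: undefined, reported as NA rather than 0
  expect_true(is.na(redundancy_coefficient(lone, "g1")))
  expect_error(redundancy_coefficient(lone, "nope"), "unknown node")
})

test_that("every node of a complete bipartite graph with both sides >= 2 has rc 1", {
  set.seed(2)
  for (i in 1:5) {
    m <- sample(2:5, 1); g <- sample(2:5, 1)
    net <- bipartite_network(tidyr::expand_grid(
      mir_id = paste0("m", 1:m), gene_id = paste0("g", 1:g)))
    met <- node_metrics(net)
    expect_true(all(met$redundancy == 1))
  }
})

test_that("redundancy equals exhaustive pair enumeration on all 3+3 graphs", {
  cells <- expand.grid(mir_id = paste0("m", 1:3), gene_id = paste0("g", 1:3),
                       stringsAsFactors = FALSE)
  for (mask in 1:(2^9 - 1)) {
    edges <- cells[as.logical(bitwAnd(mask, 2^(0:8))), ]
    expect_rc_matches_oracle(edges)
  }
})

test_that("redundancy equals the brute-force oracle on random graphs", {
  set.seed(31)
  for (i in 1:40) { # up to 5+5 nodes
    edges <- random_bipartite_edges(sample(2:5, 1), sample(2:5, 1), runif(1, 0.2, 0.8))
    if (nrow(edges) == 0) next
    expect_rc_matches_oracle(edges)
  }
  for (i in 1:30) { # up to 8+8 nodes
    edges <- random_bipartite_edges(sample(3:8, 1), sample(3:8, 1), runif(1, 0.15, 0.6))
    if (nrow(edges) == 0) next
    expect_rc_matches_oracle(edges)
  }
})

test_that("removing a fully redundant node never disconnects its neighbours", {
  set.seed(57)
  for (i in 1:20) {
    edges <- random_bipartite_edges(4, 4, 0.6)
    if (nrow(edges) == 0) next
    net <- bipartite_network(tibble::as_tibble(edges))
    met <- node_metrics(net)
    full <- met$node_id[!is.na(met$redundancy) & met$redundancy == 1 &
                          met$layer == "miR"]
    for (v in full) {
      nb <- mir_neighborhood(net, v)
      rest <- edges[edges$mir_id != v, ]
      for (a in nb) {
        for (b in setdiff(nb, a)) {
          shared <- intersect(rest$mir_id[rest$gene_id == a],
                              rest$mir_id[rest$gene_id == b])
          expect_gt(length(shared), 0)
        }
      }
    }
  }
})

test_that("degrees obey the handshake identity", {
  net <- k22()
  expect_equal(node_degree(net, "m1"), 2L)
  iso <- bipartite_network(tibble::tibble(mir_id = "m1", gene_id = "g1"),
                           mir_nodes = c("m1", "m2"), gene_nodes = "g1")
  expect_equal(node_degree(iso, "m2"), 0L)
  set.seed(13)
  edges <- random_bipartite_edges(6, 7, 0.3)
  net2 <- bipartite_network(tibble::as_tibble(edges))
  met <- node_metrics(net2)
  expect_equal(sum(met$degree[met$layer == "miR"]), nrow(edges))
  expect_equal(sum(met$degree[met$layer == "gene"]), nrow(edges))
})

test_that("connected components are counted over non-isolated nodes only", {
  two_blocks <- bipartite_network(dplyr::bind_rows(
    tidyr::expand_grid(mir_id = c("m1", "m2"), gene_id = c("g1", "g2")),
    tidyr::expand_grid(mir_id = c("m3", "m4"), gene_id = c("g3", "g4"))
  ), mir_nodes = paste0("m", 1:5), gene_nodes = paste0("g", 1:5))
  comp <- connected_components(two_blocks)
  expect_equal(max(comp$component), 2L)
  expect_false("m5" %in% comp$node_id) # isolated nodes excluded

  empty <- bipartite_network(
    tibble::tibble(mir_id = character(), gene_id = character()),
    mir_nodes = "m1", gene_nodes = "g1")
  expect_equal(nrow(connected_components(empty)), 0L)
  expect_equal(network_summary(empty)$components, 0L)

  set.seed(17)
  for (i in 1:15) {
    edges <- random_bipartite_edges(sample(2:7, 1), sample(2:7, 1), runif(1, 0.1, 0.5))
    if (nrow(edges) == 0) next
    net <- bipartite_network(tibble::as_tibble(edges))
    expect_equal(network_summary(net)$components,
                 oracle_components(net$edges))
  }
})

test_that("network summary reports the headline topology counts", {
  two_blocks <- bipartite_network(dplyr::bind_rows(
    tidyr::expand_grid(mir_id = c("m1", "m2"), gene_id = c("g1", "g2")),
    tidyr::expand_grid(mir_id = c("m3", "m4"), gene_id = c("g3", "g4"))))
  s <- network_summary(two_blocks)
  expect_equal(s$connected_mirs, 4L)
  expect_equal(s$connected_genes, 4L)
  expect_equal(s$edges, 8L)
  expect_equal(s$components, 2L)
  g <- glance(two_blocks)
  expect_equal(g$edges, 8L)
  dd <- degree_distribution(two_blocks)
  expect_equal(sum(dd$n_nodes), 8L)
})
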