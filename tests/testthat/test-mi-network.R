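test_that("equal-frequency discretization honours bin sizes and ties", {
  expect_equal(discretize_equal_frequency(c(1, 2, 3, 4), 2), c(1L, 1L, 2L, 2L))
  # all tied values share one bin
  expect_equal(discretize_equal_frequency(c(5, 5, 5, 9), 2), c(1L, 1L, 1L, 2L))
  # rank invariance under strictly monotone transforms
  set.seed(1)
  for (i in 1:25) {
    x <- rnorm(40)
    b <- sample(2:8, 1)
    expect_identical(discretize_equal_frequency(x, b),
                     discretize_equal_frequency(exp(2 * x) + 7, b))
  }
  expect_error(discretize_equal_frequency(1:10, 1), "n_bins")
  expect_error(discretize_equal_frequency(1:3, 4), "n_bins")
})

test_that("mutual information matches closed-form values", {
  # perfect dependence over two equal bins carries exactly one bit
  expect_equal(mutual_information(c(1, 2, 3, 4), c(1, 2, 3, 4), 2), 1.0)
  # joint labels uniform over all four cells: exact independence
  expect_equal(mutual_information(c(1, 2, 3, 4), c(1, 8, 2, 7), 2), 0.0)
  # self-MI saturates at log2(n_bins) when all values are distinct
  x <- c(0.3, 1.7, 2.2, 5.1, 6.0, 9.4, 9.5, 11)
  expect_equal(mutual_information(x, x, 4), log2(4))
  expect_error(mutual_information(1:4, 1:5), "equal length")
  expect_error(mutual_information(rep(1, 6), 1:6, 2), "constant")
})

test_that("mutual information equals an independent plug-in oracle", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(50); y <- 0.5 * x + rnorm(50)
    got <- mutual_information(x, y, 5)
    expect_equal(got, oracle_mi(x, y, 5), tolerance = 1e-12)
  }
})

test_that("MI is symmetric and invariant under monotone transforms", {
  set.seed(11)
  for (i in 1:100) {
    x <- runif(60); y <- runif(60)^2 + 0.3 * x
    b <- sample(2:7, 1)
    expect_equal(mutual_information(x, y, b), mutual_information(y, x, b))
    expect_equal(mutual_information(x, y, b),
                 mutual_information(log(x + 1), y^3, b))
  }
})

test_that("score matrix covers every retained miR-gene pair", {
  mk <- function(ids, n, layer, const = character()) {
    vals <- matrix(exp(rnorm(length(ids) * n)), length(ids))
    vals[ids %in% const, ] <- 1
    as_expression(tibble::as_tibble(cbind(
      tibble::tibble(transcript_id = ids),
      as.data.frame(`colnames<-`(vals, paste0("s", 1:n))))), layer)
  }
  set.seed(3)
  mir <- mk(paste0("m", 1:3), 20, "miR")
  gene <- mk(paste0("g", 1:5), 20, "gene")
  sc <- mi_scores(mir, gene, n_bins = 4)
  expect_equal(sc$total_pairs, 15L)
  expect_equal(dim(sc$mi), c(3L, 5L))
  expect_true(all(sc$mi >= 0))
  expect_equal(nrow(tidy(sc)), 15L)

  # constant transcripts are excluded from the pair universe
  gene2 <- mk(paste0("g", 1:5), 20, "gene", const = "g2")
  expect_warning(sc2 <- mi_scores(mir, gene2, n_bins = 4), "constant")
  expect_equal(sc2$total_pairs, 12L)
  expect_false("g2" %in% sc2$gene_ids)

  # sample mismatch is an error
  names(gene)[2] <- "sX"
  expect_error(mi_scores(mir, gene, 4), "sample")
})

test_that("the all-pairs kernel agrees with the scalar estimator", {
  set.seed(19)
  n <- 30
  mir <- as_expression(tibble::as_tibble(cbind(
    tibble::tibble(transcript_id = paste0("m", 1:4)),
    as.data.frame(`colnames<-`(matrix(exp(rnorm(4 * n)), 4), paste0("s", 1:n))))), "miR")
  gene <- as_expression(tibble::as_tibble(cbind(
    tibble::tibble(transcript_id = paste0("g", 1:6)),
    as.data.frame(`colnames<-`(matrix(exp(rnorm(6 * n)), 6), paste0("s", 1:n))))), "gene")
  sc <- mi_scores(mir, gene, n_bins = 5)
  mv <- as.matrix(mir[-1]); gv <- as.matrix(gene[-1])
  for (i in 1:4) {
    for (j in 1:6) {
      expect_equal(sc$mi[i, j], mutual_information(mv[i, ], gv[j, ], 5),
                   tolerance = 1e-12)
    }
  }
})

test_that("quantile thresholding keeps the m-th-largest cut with ties", {
  # distinct scores: exactly ceil((1-q) * N) edges
  set.seed(5)
  mat <- matrix(sample(seq_len(100000)) / 100000, nrow = 100)
  net <- threshold_network(make_scores(mat), quantile = 0.9999)
  expect_equal(nrow(net$edges), 10L)
  expect_true(all(net$edges$mi >= net$threshold))

  # ties at the threshold are all retained
  mat2 <- matrix(c(5, 4, 4, rep(3, 7)), nrow = 2)
  net2 <- threshold_network(make_scores(mat2), quantile = 0.85) # m = 2
  expect_equal(nrow(net2$edges), 3L)
  expect_equal(sort(net2$edges$mi), c(4, 4, 5))

  # degenerate all-equal scores: every pair becomes an edge, with a warning
  mat3 <- matrix(1, 3, 3)
  expect_warning(net3 <- threshold_network(make_scores(mat3), 0.5), "equal")
  expect_equal(nrow(net3$edges), 9L)

  expect_error(threshold_network(make_scores(mat), quantile = 1), "quantile")
})

test_that("edge count is bounded below by the quantile law on random scores", {
  set.seed(23)
  for (i in 1:20) {
    mat <- matrix(sample(1:40, 60, replace = TRUE), nrow = 6) # many ties
    q <- runif(1, 0.5, 0.99)
    net <- threshold_network(make_scores(mat), q)
    m <- ceiling((1 - q) * 60)
    expect_gte(nrow(net$edges), m)
    off_edge <- mat[mat < net$threshold]
    if (nrow(net$edges) > m) {
      # surplus edges can only come from ties at the threshold
      expect_gte(sum(mat == net$threshold), 2)
    }
    expect_true(all(off_edge < net$threshold))
  }
})

test_that("networks never contain within-layer edges or duplicate node ids", {
  expect_error(
    bipartite_network(tibble::tibble(mir_id = "a", gene_id = "b"),
                      mir_nodes = c("a", "shared"), gene_nodes = c("b", "shared")),
    "disjoint")
  expect_error(
    bipartite_network(tibble::tibble(mir_id = "g1", gene_id = "m1"),
                      mir_nodes = "m1", gene_nodes = "g1"),
    "miR node")
})
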