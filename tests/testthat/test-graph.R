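test_that("cell graphs are simple, symmetric and validated", {
  g <- cell_graph(4, rbind(c(2, 1), c(3, 4)))
  expect_equal(g$edges, rbind(c(1L, 2L), c(3L, 4L)))
  expect_error(cell_graph(3, rbind(c(1, 1))), "self-loops")
  expect_error(cell_graph(3, rbind(c(1, 4))), "out of range")
  expect_error(cell_graph(3, rbind(c(1, 2), c(2, 1))), "duplicate")
})

test_that("knn graph on collinear points links consecutive neighbours", {
  # points at 0, 1, 3, 7: nearest of each is 1->2, 2->1, 3->2, 4->3
  feats <- expression_matrix(matrix(c(0, 1, 3, 7), 4, 1),
                             normalized = "scaled")
  g <- build_knn_graph(feats, k = 1, metric = "euclidean")
  expect_equal(g$edges, rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
})

test_that("pearson knn ranks by correlation with ties to the lower index", {
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1))
  feats <- expression_matrix(m, normalized = "scaled")
  g <- build_knn_graph(feats, k = 1, metric = "pearson")
  # r(1,2) = 1; node 3 is tied between 1 and 2 at r = -1 -> picks 1
  expect_equal(g$edges, rbind(c(1L, 2L), c(1L, 3L)))

  # two nodes: forced single edge under any metric
  two <- expression_matrix(rbind(c(1, 5), c(2, 0)), normalized = "scaled")
  for (metric in c("euclidean", "manhattan", "cosine")) {
    expect_equal(build_knn_graph(two, 1, metric)$edges, rbind(c(1L, 2L)))
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  feats <- expression_matrix(matrix(runif(20), 5, 4), normalized = "x")
  expect_error(build_knn_graph(feats, k = 5), "smaller than")
  flat <- expression_matrix(rbind(c(1, 1, 1), c(1, 2, 3), c(0, 2, 4)),
                            cell_ids = c("flat", "a", "b"),
                            normalized = "x")
  expect_error(build_knn_graph(flat, 1, metric = "pearson"), "flat")
})

test_that("knn edges match the brute-force oracle across metrics and sizes", {
  set.seed(101)
  for (rep in 1:6) {
    n <- sample(8:20, 1)
    d <- sample(3:6, 1)
    v <- matrix(rnorm(n * d), n, d) + 1  # keep rows non-constant
    k <- sample(1:4, 1)
    metric <- sample(c("euclidean", "manhattan", "pearson", "cosine"), 1)
    feats <- expression_matrix(abs(v), normalized = "x")
    got <- build_knn_graph(feats, k, metric)
    expect_equal(got$edges, oracle_knn_edges(abs(v), k, metric),
                 info = sprintf("rep %d metric %s", rep, metric))
  }
})

test_that("each node selects exactly k out-neighbours before symmetrization", {
  set.seed(5)
  v <- matrix(rnorm(60), 15, 4)
  d <- as.matrix(dist(v))
  for (k in c(1, 3, 5)) {
    for (i in 1:15) {
      row <- d[i, ]; row[i] <- Inf
      expect_length(order(row, seq_len(15))[seq_len(k)], k)
    }
    # union graph degree bounded below by... not guaranteed; but every
    # node's own selection must appear as an edge
    g <- build_knn_graph(expression_matrix(v, normalized = "x"),
                         k, "euclidean")
    keys <- scvgae:::edge_keys(g$edges, 15)
    for (i in 1:15) {
      row <- d[i, ]; row[i] <- Inf
      nb <- order(row, seq_len(15))[seq_len(k)]
      own <- scvgae:::edge_keys(cbind(pmin(i, nb), pmax(i, nb)), 15)
      expect_true(all(own %in% keys))
    }
  }
})

test_that("relabelling cells yields the isomorphic graph", {
  set.seed(13)
  v <- abs(matrix(rnorm(48), 12, 4)) + 0.5
  feats <- expression_matrix(v, normalized = "x")
  g <- build_knn_graph(feats, 2, "euclidean")
  perm <- sample(12)
  feats_p <- expression_matrix(v[order(perm), , drop = FALSE], normalized = "x")
  g_p <- build_knn_graph(feats_p, 2, "euclidean")
  expect_equal(g_p$edges, permute_graph(g, perm)$edges)
})

test_that("custom edge lists are parsed, cleaned and validated", {
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(character(0), f)
  expect_equal(n_edges(read_edge_list(f, 5)), 0L)

  writeLines(c("0 1", "1 0"), f)
  g <- read_edge_list(f, 3)
  expect_equal(g$edges, rbind(c(1L, 2L)))  # duplicate collapsed, 0-based in

  writeLines(c("0 1", "2 2"), f)
  expect_warning(g2 <- read_edge_list(f, 3), "self-loop")
  expect_equal(n_edges(g2), 1L)

  writeLines(c("0 1", "0 7"), f)
  expect_error(read_edge_list(f, 3), "line 2")

  # round trip through the 0-based writer
  g3 <- cell_graph(4, rbind(c(1, 3), c(2, 4)))
  write_edge_list(g3, f)
  expect_equal(read_edge_list(f, 4)$edges, g3$edges)
})
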