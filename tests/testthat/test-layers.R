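# hand-checkable one-dimensional attention setup: W = [1], a = [1, 1],
# features h1 = 0, h2 = 1, single edge
hand_params <- function() {
  p <- gat_params(1, 1, n_heads = 1, seed = 1)
  p$heads[[1]]$W <- matrix(1, 1, 1)
  p$heads[[1]]$a_src <- 1
  p$heads[[1]]$a_dst <- 1
  p
}

test_that("attention coefficients reproduce the hand-computed softmax", {
  g <- cell_graph(2, rbind(c(1, 2)))
  h <- matrix(c(0, 1), 2, 1)
  fw <- gat_forward(h, hand_params(), g)
  a <- fw$alpha[[1]]
  # node 1: e_11 = 0, e_12 = 1 -> alpha = (1, e)/(1 + e)
  expect_equal(a[1, 1], 1 / (1 + exp(1)), tolerance = 1e-6)
  expect_equal(a[1, 2], exp(1) / (1 + exp(1)), tolerance = 1e-6)
  expect_equal(a[1, 2], 0.7311, tolerance = 1e-4)
  # forward output of node 1 = alpha_11 * 0 + alpha_12 * 1
  expect_equal(fw$output[1, 1], 0.7311, tolerance = 1e-4)
})

test_that("uniform scores give uniform attention; isolated nodes attend to themselves", {
  g <- cell_graph(4, rbind(c(1, 2), c(1, 3)))  # node 4 isolated
  p <- gat_params(2, 3, n_heads = 2, seed = 3)
  h <- matrix(1, 4, 2)  # identical features -> equal scores in a neighbourhood
  fw <- gat_forward(h, p, g)
  for (a in fw$alpha) {
    expect_equal(a[1, c(1, 2, 3)], rep(1 / 3, 3), tolerance = 1e-12)
    expect_equal(a[4, 4], 1)
  }
})

test_that("attention rows always sum to one over the neighbourhood", {
  set.seed(21)
  g <- random_toy_graph(7, 0.4, seed = 2)
  p <- gat_params(3, 4, n_heads = 3, seed = 9)
  h <- matrix(rnorm(21), 7, 3)
  fw <- gat_forward(h, p, g)
  for (a in fw$alpha) {
    expect_equal(rowSums(a), rep(1, 7), tolerance = 1e-6)
    expect_true(all(a >= 0 & a <= 1))
  }
  rec <- gat_attention(h, p, g, layer_id = 2L)
  sums <- tapply(rec$alpha, interaction(rec$head, rec$src), sum)
  expect_equal(unname(as.numeric(sums)), rep(1, 21), tolerance = 1e-6)
})

test_that("multi-head mean of identical heads equals the single head", {
  g <- cell_graph(3, rbind(c(1, 2), c(2, 3)))
  h <- matrix(rnorm(6), 3, 2)
  p1 <- gat_params(2, 2, n_heads = 1, aggregate = "mean", seed = 4)
  p2 <- gat_params(2, 2, n_heads = 2, aggregate = "mean", seed = 4)
  p2$heads[[2]] <- p1$heads[[1]]
  p2$heads[[1]] <- p1$heads[[1]]
  expect_equal(gat_forward(h, p2, g)$output, gat_forward(h, p1, g)$output,
               tolerance = 1e-12)
})

test_that("gat, gatv2 and gcn agree with dense-loop oracles on random graphs", {
  set.seed(77)
  for (rep in 1:5) {
    g <- random_toy_graph(5, 0.5, seed = rep)
    h <- matrix(rnorm(15), 5, 3)

    p <- gat_params(3, 2, n_heads = 2, seed = rep + 10)
    fw <- gat_forward(h, p, g)
    for (k in 1:2) {
      o <- oracle_gat_head(h, p$heads[[k]]$W, p$heads[[k]]$a_src,
                           p$heads[[k]]$a_dst, g)
      expect_equal(fw$alpha[[k]], o$alpha, tolerance = 1e-6)
      expect_equal(fw$output[, (2 * k - 1):(2 * k)], o$output,
                   tolerance = 1e-6)
    }

    p2 <- gatv2_params(3, 2, n_heads = 2, seed = rep + 20)
    fw2 <- gatv2_forward(h, p2, g)
    for (k in 1:2) {
      o2 <- oracle_gatv2_head(h, p2$heads[[k]]$W_l, p2$heads[[k]]$W_r,
                              p2$heads[[k]]$a, g)
      expect_equal(fw2$alpha[[k]], o2$alpha, tolerance = 1e-6)
      expect_equal(fw2$output[, (2 * k - 1):(2 * k)], o2$output,
                   tolerance = 1e-6)
    }

    W <- matrix(rnorm(6), 2, 3)
    expect_equal(gcn_forward(h, W, g), oracle_gcn(h, W, g), tolerance = 1e-6)
  }
})

test_that("gatv2 handles uniform and isolated cases", {
  g <- cell_graph(3, rbind(c(1, 2)))  # node 3 isolated
  p <- gatv2_params(2, 2, n_heads = 1, seed = 5)
  h <- matrix(1, 3, 2)
  fw <- gatv2_forward(h, p, g)
  expect_equal(fw$alpha[[1]][1, 1:2], c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(fw$alpha[[1]][3, 3], 1)
})

test_that("gcn propagation matches closed-form small cases", {
  # single node, no edges, identity weight: identity map
  g1 <- cell_graph(1)
  expect_equal(gcn_forward(matrix(3), diag(1), g1), matrix(3))
  # two connected nodes with equal features: averaging leaves them unchanged
  g2 <- cell_graph(2, rbind(c(1, 2)))
  h <- matrix(c(2, 2), 2, 1)
  expect_equal(gcn_forward(h, diag(1), g2), h, tolerance = 1e-12)
  # path graph, h = (1, 0): both nodes -> 0.5
  h2 <- matrix(c(1, 0), 2, 1)
  expect_equal(gcn_forward(h2, diag(1), g2), matrix(c(0.5, 0.5), 2, 1),
               tolerance = 1e-12)
})

test_that("self-neighbourhood with identity weights is the identity map", {
  g <- cell_graph(3)  # no edges: attention set is {self}
  p <- gat_params(2, 2, n_heads = 1, seed = 2)
  p$heads[[1]]$W <- diag(2)
  h <- matrix(rnorm(6), 3, 2)
  expect_equal(gat_forward(h, p, g)$output, h, tolerance = 1e-12)
})

test_that("layer outputs are permutation equivariant", {
  set.seed(3)
  g <- random_toy_graph(6, 0.5, seed = 6)
  h <- matrix(rnorm(18), 6, 3)
  p <- gat_params(3, 2, n_heads = 2, seed = 8)
  perm <- sample(6)
  g_p <- permute_graph(g, perm)
  h_p <- h[order(perm), , drop = FALSE]
  out <- gat_forward(h, p, g)$output
  out_p <- gat_forward(h_p, p, g_p)$output
  # node i maps to perm[i]: outputs must follow the same relabelling
  expect_equal(out_p, out[order(perm), , drop = FALSE], tolerance = 1e-9)
})

test_that("dimension mismatches are rejected", {
  g <- cell_graph(2, rbind(c(1, 2)))
  p <- gat_params(3, 2, n_heads = 1, seed = 1)
  expect_error(gat_forward(matrix(0, 2, 2), p, g), "width")
  expect_error(gcn_forward(matrix(0, 2, 2), matrix(0, 2, 3), g), "width")
})

test_that("attention records export cleanly as TSV", {
  g <- cell_graph(3, rbind(c(1, 2), c(2, 3)))
  p <- gat_params(2, 2, n_heads = 1, seed = 2)
  rec <- gat_attention(matrix(rnorm(6), 3, 2), p, g)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_attention_tsv(rec, f, header = "test")
  back <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$src, rec$src - 1L)  # 0-based at the boundary
})
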