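# Independent brute-force oracles: deliberately written as plain loops,
# structurally unlike the vectorized implementations they check.

# dense-loop graph attention: per node, per neighbour scalar arithmetic
oracle_gat_head <- function(h, W, a_src, a_dst, graph, slope = 0.2) {
  n <- nrow(h)
  adj <- adjacency_matrix(graph, self_loops = TRUE)
  out <- matrix(0, n, nrow(W))
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    e <- numeric(length(nb))
    for (m in seq_along(nb)) {
      j <- nb[m]
      si <- as.numeric(W %*% h[i, ])
      sj <- as.numeric(W %*% h[j, ])
      val <- sum(a_src * si) + sum(a_dst * sj)
      e[m] <- if (val > 0) val else slope * val
    }
    w <- exp(e - max(e))
    w <- w / sum(w)
    for (m in seq_along(nb)) {
      j <- nb[m]
      alpha[i, j] <- w[m]
      out[i, ] <- out[i, ] + w[m] * as.numeric(W %*% h[j, ])
    }
  }
  list(output = out, alpha = alpha)
}

oracle_gatv2_head <- function(h, W_l, W_r, a, graph, slope = 0.2) {
  n <- nrow(h)
  adj <- adjacency_matrix(graph, self_loops = TRUE)
  out <- matrix(0, n, nrow(W_l))
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    e <- numeric(length(nb))
    for (m in seq_along(nb)) {
      j <- nb[m]
      z <- as.numeric(W_l %*% h[i, ]) + as.numeric(W_r %*% h[j, ])
      z <- ifelse(z > 0, z, slope * z)
      e[m] <- sum(a * z)
    }
    w <- exp(e - max(e))
    w <- w / sum(w)
    for (m in seq_along(nb)) {
      j <- nb[m]
      alpha[i, j] <- w[m]
      out[i, ] <- out[i, ] + w[m] * as.numeric(W_r %*% h[j, ])
    }
  }
  list(output = out, alpha = alpha)
}

oracle_gcn <- function(h, W, graph) {
  n <- nrow(h)
  adj <- adjacency_matrix(graph, self_loops = TRUE)
  deg <- rowSums(adj)
  out <- matrix(0, n, nrow(W))
  for (i in seq_len(n)) {
    acc <- rep(0, ncol(h))
    for (j in which(adj[i, ] > 0)) {
      acc <- acc + h[j, ] / sqrt(deg[i] * deg[j])
    }
    out[i, ] <- as.numeric(W %*% acc)
  }
  out
}

# O(n^2) nearest-neighbour oracle: per-node loops over all other nodes
oracle_knn_edges <- function(v, k, metric = "euclidean") {
  n <- nrow(v)
  pick <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) {
      d[j] <- switch(metric,
        euclidean = sqrt(sum((v[i, ] - v[j, ])^2)),
        manhattan = sum(abs(v[i, ] - v[j, ])),
        pearson = 1 - suppressWarnings(stats::cor(v[i, ], v[j, ])),
        cosine = 1 - sum(v[i, ] * v[j, ]) /
          (sqrt(sum(v[i, ]^2)) * sqrt(sum(v[j, ]^2)))
      )
    }
    d[i] <- Inf
    pick[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  e <- cbind(rep(seq_len(n), k), as.vector(pick))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# pair-counting adjusted Rand index, written from the definition
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  total <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / total
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  (s11 - expected) / (maxi - expected)
}

# 2-block link-prediction fixture shared by trainer and acceptance tests
make_block_fixture <- function(graph_seed = 5, noise_seed = 17) {
  bg <- generate_block_graph(30, 2, p_in = 0.95, p_out = 0.02,
                             seed = graph_seed)
  X <- matrix(0, 30, 4)
  X[bg$labels == 0, 1:2] <- 1
  X[bg$labels == 1, 3:4] <- 1
  noise <- scvgae:::with_local_seed(noise_seed,
                                    matrix(stats::rnorm(120, sd = 0.1), 30, 4))
  list(graph = bg$graph, labels = bg$labels, X = X + noise)
}

random_toy_graph <- function(n, p = 0.5, seed = 1) {
  scvgae:::with_local_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p
    # keep the graph connected enough: always include a spanning path
    path <- cbind(seq_len(n - 1), 2:n)
    cell_graph(n, unique(rbind(pairs[keep, , drop = FALSE], path)))
  })
}
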