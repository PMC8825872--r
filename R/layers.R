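#' Create graph-attention layer parameters
#'
#' One multi-head graph-attention layer. Each head k owns a weight matrix
#' `W_k` (d_out x d_in) and an attention vector `a_k` of length `2 * d_out`,
#' stored split into its source half `a_src` (applied to the attending node
#' i) and destination half `a_dst` (applied to the attended node j), so that
#' the unnormalized score is
#' `e_ij = LeakyReLU(a_src . W h_i + a_dst . W h_j)`.
#' Weights are Glorot-uniform initialized from the given seed.
#'
#' @param d_in input feature width.
#' @param d_out per-head output width.
#' @param n_heads number of attention heads K.
#' @param aggregate `"concat"` (inner layers; output width `K * d_out`) or
#'   `"mean"` (output layers; width `d_out`).
#' @param negative_slope LeakyReLU slope for scores (default 0.2, the
#'   conventional graph-attention value).
#' @param seed integer seed for initialization.
#' @return A `gat_params` object.
#' @export
gat_params <- function(d_in, d_out, n_heads = 1,
                       aggregate = c("concat", "mean"),
                       negative_slope = 0.2, seed = 1L) {
  aggregate <- match.arg(aggregate)
  stopifnot(d_in >= 1, d_out >= 1, n_heads >= 1)
  rng <- seeded_rng(seed)
  heads <- lapply(seq_len(n_heads), function(k) {
    list(
      W = glorot(d_out, d_in, rng),
      a_src = glorot(d_out, 1, rng)[, 1],
      a_dst = glorot(d_out, 1, rng)[, 1]
    )
  })
  structure(list(heads = heads, d_in = d_in, d_out = d_out,
                 n_heads = n_heads, aggregate = aggregate,
                 negative_slope = negative_slope),
            class = "gat_params")
}

# Glorot/Xavier uniform init drawn from an isolated RNG stream
glorot <- function(nr, nc, rng) {
  lim <- sqrt(6 / (nr + nc))
  matrix(rng(nr * nc, -lim, lim), nr, nc)
}

# returns a runif-like closure with private RNG state
seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  function(n, lo, hi) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(n, lo, hi)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    x
  }
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# row-wise softmax of `scores` restricted to TRUE entries of `mask`
masked_softmax <- function(scores, mask) {
  s <- scores
  s[!mask] <- -Inf
  m <- apply(s, 1, max)
  ex <- exp(s - m)
  ex[!mask] <- 0
  ex / rowSums(ex)
}

#' Graph-attention layer forward pass
#'
#' Computes the multi-head attention update. For each head, node features
#' are linearly transformed, pairwise scores over each node's attention
#' neighbourhood (its graph neighbours plus itself) are passed through
#' LeakyReLU and softmax-normalized into coefficients `alpha_ij`, and the
#' output is the attention-weighted sum of transformed neighbour features.
#' Heads are concatenated (`aggregate = "concat"`) or averaged
#' (`aggregate = "mean"`).
#'
#' @param h numeric matrix of node features, `n_nodes` x `d_in`.
#' @param params a [gat_params()] object.
#' @param graph a `cell_graph` over the same nodes.
#' @param activation optional elementwise function applied to the output
#'   (the encoder applies ReLU *between* layers instead; see
#'   [vgae_encode()]).
#' @param keep_cache keep intermediates for backpropagation (internal).
#' @return A list with `output` (node features), `alpha` (list of dense
#'   `n x n` coefficient matrices, one per head; zero outside each
#'   neighbourhood) and, if requested, `cache`.
#' @export
gat_forward <- function(h, params, graph, activation = NULL,
                        keep_cache = FALSE) {
  h <- as.matrix(h)
  stopifnot(inherits(params, "gat_params"), inherits(graph, "cell_graph"))
  if (ncol(h) != params$d_in) {
    stop(sprintf("feature width (%d) does not match layer d_in (%d)",
                 ncol(h), params$d_in))
  }
  if (nrow(h) != graph$n_nodes) stop("feature rows must match graph nodes")
  mask <- adjacency_matrix(graph, self_loops = TRUE) > 0
  outs <- vector("list", params$n_heads)
  alphas <- vector("list", params$n_heads)
  caches <- if (keep_cache) vector("list", params$n_heads) else NULL
  for (k in seq_len(params$n_heads)) {
    p <- params$heads[[k]]
    S <- h %*% t(p$W)                         # n x d_out
    f <- drop(S %*% p$a_src)                  # score part of the attending node
    g <- drop(S %*% p$a_dst)                  # score part of the attended node
    pre <- outer(f, rep(1, length(g))) + outer(rep(1, length(f)), g)
    E <- leaky_relu(pre, params$negative_slope)
    alpha <- masked_softmax(E, mask)
    outs[[k]] <- alpha %*% S
    alphas[[k]] <- alpha
    if (keep_cache) {
      caches[[k]] <- list(S = S, pre = pre, alpha = alpha)
    }
  }
  output <- if (params$aggregate == "concat") {
    do.call(cbind, outs)
  } else {
    Reduce(`+`, outs) / params$n_heads
  }
  if (!is.null(activation)) output <- activation(output)
  res <- list(output = output, alpha = alphas)
  if (keep_cache) {
    res$cache <- list(h = h, mask = mask, heads = caches, params = params,
                      activation = activation)
  }
  res
}

# Backward pass through one GAT layer (no output activation assumed; the
# encoder handles inter-layer ReLU itself). d_out_grad is the gradient of
# the loss w.r.t. the layer output. Returns gradient w.r.t. the input
# features plus per-head parameter gradients.
gat_backward <- function(cache, d_out_grad) {
  params <- cache$params
  n_heads <- params$n_heads
  d_out <- params$d_out
  h <- cache$h
  d_h <- matrix(0, nrow(h), ncol(h))
  grads <- vector("list", n_heads)
  for (k in seq_len(n_heads)) {
    if (params$aggregate == "concat") {
      cols <- ((k - 1) * d_out + 1):(k * d_out)
      dO <- d_out_grad[, cols, drop = FALSE]
    } else {
      dO <- d_out_grad / n_heads
    }
    p <- params$heads[[k]]
    ck <- cache$heads[[k]]
    S <- ck$S; alpha <- ck$alpha
    d_alpha <- dO %*% t(S)
    d_S <- t(alpha) %*% dO
    rowdot <- rowSums(d_alpha * alpha)
    d_E <- alpha * (d_alpha - rowdot)          # softmax backward; 0 off-mask
    d_pre <- d_E * leaky_relu_grad(ck$pre, params$negative_slope)
    d_f <- rowSums(d_pre)
    d_g <- colSums(d_pre)
    d_S <- d_S + outer(d_f, p$a_src) + outer(d_g, p$a_dst)
    grads[[k]] <- list(
      W = t(d_S) %*% h,
      a_src = drop(t(S) %*% d_f),
      a_dst = drop(t(S) %*% d_g)
    )
    d_h <- d_h + d_S %*% p$W
  }
  list(d_input = d_h, heads = grads)
}

#' Attention coefficients of a graph-attention layer
#'
#' Runs only the attention part of [gat_forward()] and returns the
#' coefficients as a tidy record.
#'
#' @inheritParams gat_forward
#' @param layer_id identifier stored in the record.
#' @return A data frame (class `attention_record`) with columns `layer`,
#'   `head`, `src`, `dst`, `alpha`; row (i, j) holds the coefficient with
#'   which node i attends to node j (self-loops included). Within every
#'   (layer, head, src) group the coefficients sum to 1.
#' @export
gat_attention <- function(h, params, graph, layer_id = 1L) {
  fw <- gat_forward(h, params, graph)
  attention_record(fw$alpha, layer_id = layer_id)
}

#' Assemble an attention record from dense coefficient matrices
#'
#' @param alpha_list list of dense `n x n` attention matrices, one per head.
#' @param layer_id integer layer identifier.
#' @return An `attention_record` data frame (see [gat_attention()]).
#' @export
attention_record <- function(alpha_list, layer_id = 1L) {
  recs <- lapply(seq_along(alpha_list), function(k) {
    a <- alpha_list[[k]]
    idx <- which(a > 0, arr.ind = TRUE)
    data.frame(layer = layer_id, head = k,
               src = idx[, 1], dst = idx[, 2],
               alpha = a[idx])
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$layer, out$head, out$src, out$dst), ]
  rownames(out) <- NULL
  class(out) <- c("attention_record", "data.frame")
  out
}

#' GATv2 layer forward pass
#'
#' Variant attention scoring in which the nonlinearity is applied before the
#' attention vector: `e_ij = a . LeakyReLU(W_l h_i + W_r h_j)`, making the
#' attention function universal rather than restricted to a fixed ranking.
#' Aggregation and normalization follow [gat_forward()].
#'
#' @param h node features (`n x d_in`).
#' @param params a `gatv2_params` object from [gatv2_params()].
#' @param graph a `cell_graph`.
#' @param activation optional elementwise output activation.
#' @return A list with `output` and `alpha` as in [gat_forward()].
#' @export
gatv2_forward <- function(h, params, graph, activation = NULL) {
  h <- as.matrix(h)
  stopifnot(inherits(params, "gatv2_params"))
  if (ncol(h) != params$d_in) {
    stop(sprintf("feature width (%d) does not match layer d_in (%d)",
                 ncol(h), params$d_in))
  }
  if (nrow(h) != graph$n_nodes) stop("feature rows must match graph nodes")
  mask <- adjacency_matrix(graph, self_loops = TRUE) > 0
  n <- nrow(h)
  outs <- vector("list", params$n_heads)
  alphas <- vector("list", params$n_heads)
  for (k in seq_len(params$n_heads)) {
    p <- params$heads[[k]]
    Sl <- h %*% t(p$W_l)
    Sr <- h %*% t(p$W_r)
    E <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- which(mask[i, ])
      z <- sweep(Sr[nb, , drop = FALSE], 2, Sl[i, ], "+")
      E[i, nb] <- leaky_relu(z, params$negative_slope) %*% p$a
    }
    alpha <- masked_softmax(E, mask)
    outs[[k]] <- alpha %*% Sr
    alphas[[k]] <- alpha
  }
  output <- if (params$aggregate == "concat") do.call(cbind, outs)
            else Reduce(`+`, outs) / params$n_heads
  if (!is.null(activation)) output <- activation(output)
  list(output = output, alpha = alphas)
}

#' Create GATv2 layer parameters
#'
#' @inheritParams gat_params
#' @return A `gatv2_params` object with per-head `W_l`, `W_r`
#'   (`d_out x d_in`, the left/right halves of the joint transform of
#'   `[h_i || h_j]`) and attention vector `a` of length `d_out`.
#' @export
gatv2_params <- function(d_in, d_out, n_heads = 1,
                         aggregate = c("concat", "mean"),
                         negative_slope = 0.2, seed = 1L) {
  aggregate <- match.arg(aggregate)
  rng <- seeded_rng(seed)
  heads <- lapply(seq_len(n_heads), function(k) {
    list(W_l = glorot(d_out, d_in, rng),
         W_r = glorot(d_out, d_in, rng),
         a = glorot(d_out, 1, rng)[, 1])
  })
  structure(list(heads = heads, d_in = d_in, d_out = d_out,
                 n_heads = n_heads, aggregate = aggregate,
                 negative_slope = negative_slope),
            class = "gatv2_params")
}

#' Graph-convolution (GCN) layer forward pass
#'
#' Symmetric-normalized propagation with self-loops:
#' `H' = D^(-1/2) (A + I) D^(-1/2) H W` where `D` is the degree matrix of
#' `A + I`.
#'
#' @param h node features (`n x d_in`).
#' @param weight `d_out x d_in` weight matrix (applied as `H W^T`).
#' @param graph a `cell_graph`.
#' @param activation optional elementwise output activation.
#' @return Node feature matrix `n x d_out`.
#' @export
gcn_forward <- function(h, weight, graph, activation = NULL) {
  h <- as.matrix(h)
  weight <- as.matrix(weight)
  if (ncol(h) != ncol(weight)) {
    stop(sprintf("feature width (%d) does not match weight columns (%d)",
                 ncol(h), ncol(weight)))
  }
  if (nrow(h) != graph$n_nodes) stop("feature rows must match graph nodes")
  a_tilde <- adjacency_matrix(graph, self_loops = TRUE)
  d_inv_sqrt <- 1 / sqrt(rowSums(a_tilde))
  prop <- a_tilde * outer(d_inv_sqrt, d_inv_sqrt)
  out <- prop %*% h %*% t(weight)
  if (!is.null(activation)) out <- activation(out)
  out
}

#' Write an attention record to TSV
#'
#' Columns: layer, head, src, dst, alpha. Node indices are written 0-based
#' to match the edge-list convention of graph viewers.
#'
#' @param attn an `attention_record`.
#' @param path output path.
#' @param header optional `#`-prefixed comment line.
#' @return Invisibly, `path`.
#' @export
write_attention_tsv <- function(attn, path, header = NULL) {
  out <- as.data.frame(attn)
  out$src <- out$src - 1L
  out$dst <- out$dst - 1L
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
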