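#' Initialize a variational graph autoencoder
#'
#' The encoder is a stack of multi-head graph-attention layers: one or more
#' inner layers that concatenate their heads (so layer i outputs
#' `K_i * D_i` features), followed by two parallel output layers that
#' average their heads and produce the per-cell posterior parameters `mu`
#' and `log sigma`, each `n x latent_dim`. ReLU is applied between layers
#' (not after the first layer's input, and not on the outputs). The decoder
#' is the parameter-free inner product: the probability of an edge (i, j)
#' is `sigmoid(z_i . z_j)`.
#'
#' @param d_in input feature width (number of node-feature genes).
#' @param hidden_dims integer vector of per-head output widths of the inner
#'   layers (at least one).
#' @param latent_dim latent width L (per-head width of the mu/sigma layers).
#' @param n_heads attention heads; a single value recycled over all layers,
#'   or one value per layer (inner layers plus one shared value for the two
#'   output layers).
#' @param negative_slope LeakyReLU slope of the attention scores.
#' @param use_feature_recon also create a linear feature-reconstruction
#'   decoder head mapping latents back to the `d_in` input features.
#' @param seed integer seed for weight initialization.
#' @return A `vgae_model` object.
#' @export
vgae_init <- function(d_in, hidden_dims = c(32, 32), latent_dim = 16,
                      n_heads = 2, negative_slope = 0.2,
                      use_feature_recon = FALSE, seed = 1L) {
  n_inner <- length(hidden_dims)
  stopifnot(n_inner >= 1, latent_dim >= 1)
  n_layers <- n_inner + 1L
  if (length(n_heads) == 1) n_heads <- rep(n_heads, n_layers)
  if (length(n_heads) != n_layers) {
    stop("n_heads must have length 1 or length(hidden_dims) + 1")
  }
  inner <- vector("list", n_inner)
  width <- d_in
  for (i in seq_len(n_inner)) {
    inner[[i]] <- gat_params(width, hidden_dims[i], n_heads[i],
                             aggregate = "concat",
                             negative_slope = negative_slope,
                             seed = seed + i)
    width <- hidden_dims[i] * n_heads[i]
  }
  k_out <- n_heads[n_layers]
  mu_layer <- gat_params(width, latent_dim, k_out, aggregate = "mean",
                         negative_slope = negative_slope,
                         seed = seed + n_inner + 1L)
  sigma_layer <- gat_params(width, latent_dim, k_out, aggregate = "mean",
                            negative_slope = negative_slope,
                            seed = seed + n_inner + 2L)
  recon_net <- NULL
  if (use_feature_recon) {
    rng <- seeded_rng(seed + n_inner + 3L)
    recon_net <- list(W = glorot(d_in, latent_dim, rng), b = rep(0, d_in))
  }
  structure(list(inner = inner, mu_layer = mu_layer,
                 sigma_layer = sigma_layer, recon_net = recon_net,
                 d_in = d_in, hidden_dims = hidden_dims,
                 latent_dim = latent_dim, n_heads = n_heads,
                 negative_slope = negative_slope, seed = seed),
            class = "vgae_model")
}

#' @method print vgae_model
#' @export
print.vgae_model <- function(x, ...) {
  cat(sprintf("<vgae_model> %d -> [%s] -> %d latent | heads %s%s\n",
              x$d_in, paste(x$hidden_dims, collapse = ", "), x$latent_dim,
              paste(x$n_heads, collapse = "/"),
              if (!is.null(x$recon_net)) " | feature recon" else ""))
  invisible(x)
}

#' Encode node features to posterior parameters
#'
#' Runs the attention-layer stack: `X_1 = GAT_1(X, A)`,
#' `X_i = GAT_i(ReLU(X_{i-1}), A)` for the remaining inner layers, then
#' `mu = GAT_mu(ReLU(X_N), A)` and `log sigma = GAT_sigma(ReLU(X_N), A)`
#' with head averaging.
#'
#' @param model a `vgae_model`.
#' @param X node features (`n x d_in`).
#' @param graph a `cell_graph`.
#' @param keep_cache retain intermediates for backpropagation (internal).
#' @return A list with `mu`, `log_sigma` (both `n x latent_dim`),
#'   `attention` (an `attention_record` over all layers/heads) and, if
#'   requested, `cache`.
#' @export
vgae_encode <- function(model, X, graph, keep_cache = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != model$d_in) {
    stop(sprintf("input width (%d) does not match model d_in (%d)",
                 ncol(X), model$d_in))
  }
  h <- X
  inner_fw <- vector("list", length(model$inner))
  acts <- vector("list", length(model$inner))  # post-ReLU inputs per layer
  records <- list()
  for (i in seq_along(model$inner)) {
    inp <- if (i == 1) h else pmax(h, 0)
    acts[[i]] <- inp
    fw <- gat_forward(inp, model$inner[[i]], graph, keep_cache = keep_cache)
    inner_fw[[i]] <- fw
    records[[i]] <- attention_record(fw$alpha, layer_id = i)
    h <- fw$output
  }
  top <- pmax(h, 0)
  fw_mu <- gat_forward(top, model$mu_layer, graph, keep_cache = keep_cache)
  fw_sig <- gat_forward(top, model$sigma_layer, graph, keep_cache = keep_cache)
  n_inner <- length(model$inner)
  records[[n_inner + 1]] <- attention_record(fw_mu$alpha, layer_id = n_inner + 1L)
  records[[n_inner + 2]] <- attention_record(fw_sig$alpha, layer_id = n_inner + 2L)
  attn <- do.call(rbind, records)
  class(attn) <- c("attention_record", "data.frame")
  out <- list(mu = fw_mu$output, log_sigma = fw_sig$output, attention = attn)
  if (keep_cache) {
    out$cache <- list(inner_fw = inner_fw, acts = acts, pre_relu = h,
                      top = top, fw_mu = fw_mu, fw_sig = fw_sig)
  }
  out
}

#' Sample latent variables via the reparameterization trick
#'
#' `Z = mu + exp(log_sigma) * eps` with `eps ~ N(0, I)` drawn from the given
#' seed, so identical seeds give identical samples.
#'
#' @param enc list with `mu` and `log_sigma` (from [vgae_encode()]).
#' @param seed integer seed for the noise draw (ignored when `epsilon` is
#'   supplied).
#' @param epsilon optional pre-drawn noise matrix of the same shape as `mu`
#'   (test/backprop hook).
#' @return A list with the sample `Z`, the `epsilon` used, and the `seed`.
#' @export
reparameterize <- function(enc, seed = 1L, epsilon = NULL) {
  mu <- enc$mu
  ls <- enc$log_sigma
  stopifnot(all(dim(mu) == dim(ls)))
  if (is.null(epsilon)) {
    rng_state <- NULL
    epsilon <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      e <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      e
    })
  }
  list(Z = mu + exp(ls) * epsilon, epsilon = epsilon, seed = seed)
}

#' Inner-product edge probability
#'
#' @param z_i,z_j latent vectors of equal length.
#' @return `sigmoid(z_i . z_j)`, the decoded probability that the edge
#'   exists.
#' @export
decode_edge_prob <- function(z_i, z_j) {
  if (length(z_i) != length(z_j)) stop("latent vectors must have equal length")
  stats::plogis(sum(z_i * z_j))
}

# vectorized decoder over an edge matrix (rows = pairs, 1-based indices)
decode_edges <- function(Z, edges) {
  if (!nrow(edges)) return(numeric(0))
  stats::plogis(rowSums(Z[edges[, 1], , drop = FALSE] *
                        Z[edges[, 2], , drop = FALSE]))
}

#' Kullback-Leibler regularization loss
#'
#' KL divergence of the per-cell Gaussian posterior `N(mu, diag(sigma^2))`
#' from the standard-normal prior, `0.5 * sum(mu^2 + sigma^2 - 1 -
#' log sigma^2)` summed over latent dimensions and averaged over cells.
#'
#' @param enc list with `mu` and `log_sigma`.
#' @return Non-negative scalar.
#' @export
kl_loss <- function(enc) {
  mu <- enc$mu
  ls <- enc$log_sigma
  n <- nrow(mu)
  sum(0.5 * (mu^2 + exp(2 * ls) - 1 - 2 * ls)) / n
}

#' Maximum mean discrepancy regularization loss
#'
#' Biased MMD^2 estimate with a Gaussian kernel
#' `k(x, y) = exp(-||x - y||^2 / (2 * bandwidth))` between the latent
#' sample rows and draws from the standard-normal prior. Non-negative by
#' construction; 0 when the two samples coincide.
#'
#' @param Z latent sample matrix (`n x L`).
#' @param prior_samples matrix of prior draws with the same column count.
#' @param bandwidth kernel bandwidth (squared length scale). `NULL` uses the
#'   latent dimension L; `"median"` uses the median heuristic (median
#'   squared pairwise distance of the pooled sample).
#' @return Non-negative scalar.
#' @export
mmd_loss <- function(Z, prior_samples, bandwidth = NULL) {
  Z <- as.matrix(Z); P <- as.matrix(prior_samples)
  if (!nrow(Z) || !nrow(P)) stop("both sample sets must be non-empty")
  if (ncol(Z) != ncol(P)) stop("sample sets must have equal dimensionality")
  if (is.null(bandwidth)) bandwidth <- ncol(Z)
  if (identical(bandwidth, "median")) {
    pooled <- rbind(Z, P)
    d2 <- as.matrix(stats::dist(pooled))^2
    bandwidth <- stats::median(d2[upper.tri(d2)])
    if (bandwidth == 0) bandwidth <- 1
  }
  kzz <- gaussian_kernel_mat(Z, Z, bandwidth)
  kpp <- gaussian_kernel_mat(P, P, bandwidth)
  kzp <- gaussian_kernel_mat(Z, P, bandwidth)
  max(mean(kzz) + mean(kpp) - 2 * mean(kzp), 0)
}

gaussian_kernel_mat <- function(A, B, bandwidth) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * bandwidth))
}

#' Edge-reconstruction loss (binary cross entropy with negative sampling)
#'
#' `-(sum log p_pos + sum log(1 - p_neg)) / E` where probabilities come from
#' the inner-product decoder, `E` is the total number of scored edges
#' (positive plus negative), and probabilities are clamped to
#' `[1e-15, 1 - 1e-15]` so the loss stays finite.
#'
#' @param Z latent matrix (`n x L`).
#' @param pos_edges two-column matrix of observed edges (1-based); must be
#'   non-empty.
#' @param neg_edges two-column matrix of sampled non-edges; may be empty.
#' @return Non-negative scalar.
#' @export
recon_loss <- function(Z, pos_edges, neg_edges = matrix(integer(), ncol = 2)) {
  pos_edges <- matrix(as.integer(pos_edges), ncol = 2)
  neg_edges <- matrix(as.integer(neg_edges), ncol = 2)
  if (!nrow(pos_edges)) stop("pos_edges must be non-empty")
  clamp <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-15)
  p_pos <- clamp(decode_edges(Z, pos_edges))
  e_total <- nrow(pos_edges) + nrow(neg_edges)
  s <- -sum(log(p_pos))
  if (nrow(neg_edges)) {
    p_neg <- clamp(decode_edges(Z, neg_edges))
    s <- s - sum(log(1 - p_neg))
  }
  s / e_total
}

#' Feature-reconstruction loss
#'
#' Mean squared error between `recon_net(Z)` (a linear map from the latent
#' space back to the input features) and the input `X`. Optional addition to
#' the base loss; off by default since reconstructing only the graph is the
#' standard formulation.
#'
#' @param Z latent matrix (`n x L`).
#' @param X input feature matrix (`n x d_in`).
#' @param recon_net list with `W` (`d_in x L`) and bias `b` (length
#'   `d_in`).
#' @return Non-negative scalar MSE.
#' @export
feature_recon_loss <- function(Z, X, recon_net) {
  Z <- as.matrix(Z); X <- as.matrix(X)
  pred <- Z %*% t(recon_net$W)
  pred <- sweep(pred, 2, recon_net$b, "+")
  if (!all(dim(pred) == dim(X))) {
    stop("recon_net output width does not match feature width")
  }
  mean((pred - X)^2)
}

#' Total training loss
#'
#' Regularization (KL or MMD) plus edge-reconstruction BCE, plus the
#' feature-reconstruction MSE when enabled. The returned value is the
#' quantity minimized by the trainer.
#'
#' @param components named list with `reg`, `recon` and optionally
#'   `feature_recon` scalars.
#' @param reg_kind `"kl"` or `"mmd"` (recorded; the caller computes the
#'   matching `reg` component).
#' @param use_feature_recon add the `feature_recon` component.
#' @return Scalar loss.
#' @export
total_loss <- function(components, reg_kind = c("kl", "mmd"),
                       use_feature_recon = FALSE) {
  reg_kind <- match.arg(reg_kind)
  out <- components$reg + components$recon
  if (use_feature_recon) {
    if (is.null(components$feature_recon)) {
      stop("feature_recon component missing")
    }
    out <- out + components$feature_recon
  }
  out
}
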