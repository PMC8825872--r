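#' Create a training configuration
#'
#' Bundles every knob of the workflow: graph settings (recorded for
#' provenance; graph construction itself happens upstream), encoder shape,
#' loss choice, optimization settings and the master seed from which all
#' randomness (initialization, negative sampling, reparameterization noise,
#' holdout split) is derived.
#'
#' @param hidden_dims per-head widths of the inner attention layers.
#' @param n_heads attention heads (scalar or per-layer vector).
#' @param latent_dim latent width L.
#' @param reg_kind `"kl"` (default) or `"mmd"` regularization.
#' @param use_feature_recon add the feature-reconstruction MSE term.
#' @param epochs full-graph gradient steps (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed master integer seed.
#' @param holdout_fraction fraction of edges held out for convergence
#'   monitoring (in `[0, 0.5)`; 0 trains on every edge).
#' @param mmd_bandwidth Gaussian-kernel bandwidth for the MMD loss (`NULL`
#'   = latent dimension; `"median"` = median heuristic).
#' @param reg_weight weight of the regularization term in the minimized
#'   objective. `NULL` (default) uses the original variational
#'   graph-autoencoder convention: `1 / n_nodes` for the KL term (without
#'   this down-weighting the KL pressure collapses the posterior to the
#'   prior on small graphs) and 1 for MMD.
#' @param k,khvg,n_hvg graph/preprocessing settings carried for provenance
#'   (defaults: 5 neighbours, 250 graph genes, 250 feature genes).
#' @return A `training_config` list.
#' @export
training_config <- function(hidden_dims = c(32, 32), n_heads = 2,
                            latent_dim = 16,
                            reg_kind = c("kl", "mmd"),
                            use_feature_recon = FALSE,
                            epochs = 200, learning_rate = 1e-3,
                            seed = 1L, holdout_fraction = 0,
                            mmd_bandwidth = NULL, reg_weight = NULL,
                            k = 5, khvg = 250, n_hvg = 250) {
  reg_kind <- match.arg(reg_kind)
  stopifnot(epochs >= 1, latent_dim >= 1,
            holdout_fraction >= 0, holdout_fraction < 0.5)
  structure(list(hidden_dims = hidden_dims, n_heads = n_heads,
                 latent_dim = latent_dim, reg_kind = reg_kind,
                 use_feature_recon = use_feature_recon, epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 holdout_fraction = holdout_fraction,
                 mmd_bandwidth = mmd_bandwidth, reg_weight = reg_weight,
                 k = k, khvg = khvg, n_hvg = n_hvg),
            class = "training_config")
}

#' Sample negative (non-)edges uniformly
#'
#' Draws `n` distinct unordered node pairs that are not edges of `graph`
#' and not self-loops, uniformly by seeded rejection sampling.
#'
#' @param graph a `cell_graph`.
#' @param n number of negative edges required.
#' @param seed integer seed.
#' @return Two-column matrix of 1-based node pairs (each row `i < j`).
#' @export
sample_negative_edges <- function(graph, n, seed = 1L) {
  nn <- graph$n_nodes
  total_pairs <- nn * (nn - 1) / 2
  m <- nrow(graph$edges)
  avail <- total_pairs - m
  if (avail == 0) stop("graph is complete; no negative edges exist")
  if (n > avail) {
    stop(sprintf("requested %d negative edges but only %d non-edges exist",
                 n, avail))
  }
  pos_keys <- edge_keys(graph$edges, nn)
  with_local_seed(seed, {
    found <- integer(0)
    while (length(found) < n) {
      draw <- ceiling(max(4 * (n - length(found)), 16) * 1.2)
      i <- sample.int(nn, draw, replace = TRUE)
      j <- sample.int(nn, draw, replace = TRUE)
      ok <- i != j
      cand <- cbind(pmin(i[ok], j[ok]), pmax(i[ok], j[ok]))
      keys <- edge_keys(cand, nn)
      keep <- !(keys %in% pos_keys) & !(keys %in% found)
      keep <- keep & !duplicated(keys)
      found <- c(found, keys[keep])
    }
    found <- found[seq_len(n)]
    keys_to_edges(found, nn)
  })
}

edge_keys <- function(edges, n) {
  if (!nrow(edges)) return(numeric(0))
  (pmin(edges[, 1], edges[, 2]) - 1) * n + pmax(edges[, 1], edges[, 2])
}

keys_to_edges <- function(keys, n) {
  i <- (keys - 1) %/% n + 1
  j <- keys - (i - 1) * n
  cbind(as.integer(i), as.integer(j))
}

#' Split edges into a training graph and a held-out set
#'
#' Removes a random fraction of edges for convergence monitoring; the node
#' set is unchanged. Seeded and reproducible.
#'
#' @param graph a `cell_graph`.
#' @param fraction fraction of edges to hold out (`floor(fraction * m)`
#'   edges); must leave at least one training edge.
#' @param seed integer seed.
#' @return List with `train` (a `cell_graph`) and `holdout` (two-column
#'   edge matrix, possibly empty).
#' @export
holdout_split <- function(graph, fraction, seed = 1L) {
  m <- nrow(graph$edges)
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n_hold <- floor(fraction * m)
  if (m - n_hold < 1) stop("holdout fraction leaves no training edges")
  if (n_hold == 0) {
    return(list(train = graph, holdout = matrix(integer(), ncol = 2)))
  }
  idx <- with_local_seed(seed, sample.int(m, n_hold))
  list(train = cell_graph(graph$n_nodes, graph$edges[-idx, , drop = FALSE]),
       holdout = graph$edges[idx, , drop = FALSE])
}

# ---- loss + analytic gradients -------------------------------------------

# Extract the trainable parameter tree of a model (nested numeric leaves)
model_params <- function(model) {
  lay <- function(p) lapply(p$heads, function(h) list(W = h$W, a_src = h$a_src, a_dst = h$a_dst))
  out <- list(inner = lapply(model$inner, lay),
              mu = lay(model$mu_layer), sigma = lay(model$sigma_layer))
  if (!is.null(model$recon_net)) out$recon <- model$recon_net
  out
}

set_model_params <- function(model, params) {
  for (i in seq_along(model$inner)) {
    for (k in seq_along(model$inner[[i]]$heads)) {
      model$inner[[i]]$heads[[k]] <- params$inner[[i]][[k]]
    }
  }
  for (k in seq_along(model$mu_layer$heads)) {
    model$mu_layer$heads[[k]] <- params$mu[[k]]
  }
  for (k in seq_along(model$sigma_layer$heads)) {
    model$sigma_layer$heads[[k]] <- params$sigma[[k]]
  }
  if (!is.null(model$recon_net)) model$recon_net <- params$recon
  model
}

# Full-model loss and analytic gradients for one training step.
# epsilon is the reparameterization noise (fixed by the caller so the loss
# is a deterministic function of the parameters).
vgae_loss_and_grads <- function(model, X, graph, pos_edges, neg_edges,
                                epsilon, reg_kind = "kl",
                                prior_samples = NULL, mmd_bandwidth = NULL,
                                use_feature_recon = FALSE, reg_weight = 1) {
  enc <- vgae_encode(model, X, graph, keep_cache = TRUE)
  mu <- enc$mu; ls <- enc$log_sigma
  n <- nrow(mu)
  Z <- mu + exp(ls) * epsilon

  # reconstruction BCE and its gradient w.r.t. Z
  e_total <- nrow(pos_edges) + nrow(neg_edges)
  clamp <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-15)
  p_pos <- clamp(decode_edges(Z, pos_edges))
  recon <- -sum(log(p_pos))
  dZ <- matrix(0, n, ncol(Z))
  # d/d(z_i . z_j) of -log sigmoid = -(1 - p)
  cpos <- -(1 - p_pos) / e_total
  for (r in seq_len(nrow(pos_edges))) {
    i <- pos_edges[r, 1]; j <- pos_edges[r, 2]
    dZ[i, ] <- dZ[i, ] + cpos[r] * Z[j, ]
    dZ[j, ] <- dZ[j, ] + cpos[r] * Z[i, ]
  }
  if (nrow(neg_edges)) {
    p_neg <- clamp(decode_edges(Z, neg_edges))
    recon <- recon - sum(log(1 - p_neg))
    cneg <- p_neg / e_total
    for (r in seq_len(nrow(neg_edges))) {
      i <- neg_edges[r, 1]; j <- neg_edges[r, 2]
      dZ[i, ] <- dZ[i, ] + cneg[r] * Z[j, ]
      dZ[j, ] <- dZ[j, ] + cneg[r] * Z[i, ]
    }
  }
  recon <- recon / e_total

  # regularization and its gradient
  if (reg_kind == "kl") {
    reg <- sum(0.5 * (mu^2 + exp(2 * ls) - 1 - 2 * ls)) / n
    d_mu_reg <- reg_weight * mu / n
    d_ls_reg <- reg_weight * (exp(2 * ls) - 1) / n
    d_Z_reg <- 0
  } else {
    if (is.null(prior_samples)) stop("MMD regularization needs prior_samples")
    bw <- if (is.null(mmd_bandwidth)) ncol(Z) else mmd_bandwidth
    if (identical(bw, "median")) {
      pooled <- rbind(Z, prior_samples)
      d2 <- as.matrix(stats::dist(pooled))^2
      bw <- stats::median(d2[upper.tri(d2)])
      if (bw == 0) bw <- 1
    }
    P <- prior_samples
    kzz <- gaussian_kernel_mat(Z, Z, bw)
    kpp <- gaussian_kernel_mat(P, P, bw)
    kzp <- gaussian_kernel_mat(Z, P, bw)
    nz <- nrow(Z); np <- nrow(P)
    reg <- mean(kzz) + mean(kpp) - 2 * mean(kzp)
    # d mean(kzz)/dz_i = (2 / (nz^2 * bw)) * sum_j kzz_ij (z_j - z_i);
    # the -2*mean(kzp) term contributes (2/(nz*np*bw)) * sum_j kzp_ij (z_i - p_j)
    d_Z_reg <- (2 / (nz^2 * bw)) * (kzz %*% Z - rowSums(kzz) * Z) +
      (2 / (nz * np * bw)) * (rowSums(kzp) * Z - kzp %*% P)
    d_Z_reg <- reg_weight * d_Z_reg
    d_mu_reg <- 0
    d_ls_reg <- 0
  }

  loss <- reg_weight * reg + recon
  feat <- NULL
  d_Z_feat <- 0
  recon_grads <- NULL
  if (use_feature_recon) {
    rn <- model$recon_net
    if (is.null(rn)) stop("model has no feature-reconstruction network")
    pred <- sweep(Z %*% t(rn$W), 2, rn$b, "+")
    resid <- pred - X
    feat <- mean(resid^2)
    dpred <- 2 * resid / length(resid)
    d_Z_feat <- dpred %*% rn$W
    recon_grads <- list(W = t(dpred) %*% Z, b = colSums(dpred))
    loss <- loss + feat
  }

  dZ_total <- dZ + d_Z_reg + d_Z_feat
  d_mu <- dZ_total + d_mu_reg
  d_ls <- dZ_total * epsilon * exp(ls) + d_ls_reg

  # back through the two output layers
  bw_mu <- gat_backward(enc$cache$fw_mu$cache, d_mu)
  bw_sig <- gat_backward(enc$cache$fw_sig$cache, d_ls)
  d_top <- bw_mu$d_input + bw_sig$d_input
  d_h <- d_top * (enc$cache$pre_relu > 0)   # ReLU before the output layers

  inner_grads <- vector("list", length(model$inner))
  for (i in rev(seq_along(model$inner))) {
    bw <- gat_backward(enc$cache$inner_fw[[i]]$cache, d_h)
    inner_grads[[i]] <- bw$heads
    if (i > 1) {
      d_h <- bw$d_input * (enc$cache$acts[[i]] > 0)  # ReLU between layers
    }
  }

  grads <- list(inner = inner_grads, mu = bw_mu$heads, sigma = bw_sig$heads)
  if (use_feature_recon) grads$recon <- recon_grads
  list(loss = loss,
       components = list(reg = reg, recon = recon, feature_recon = feat),
       grads = grads, mu = mu, log_sigma = ls, Z = Z,
       attention = enc$attention)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# ---- training loop --------------------------------------------------------

#' Train the variational graph autoencoder
#'
#' Full-graph training: every epoch encodes all cells, samples one fresh
#' set of negative edges (as many as there are positive edges), takes one
#' Adam step on the total loss, and optionally scores held-out edges by
#' ROC-AUC of the inner-product decoder against an equal number of
#' negatives. The deterministic embedding returned for downstream analysis
#' is the posterior mean `mu` of the trained model (not a noisy sample).
#'
#' @param X node-feature matrix (`n_cells` rows) or an `sc_expr`.
#' @param graph a `cell_graph` over the same cells.
#' @param config a [training_config()].
#' @return A `vgae_fit` list: `model` (trained), `embedding` (final `mu`),
#'   `attention` (record from the final forward pass), `history` (per-epoch
#'   data frame with loss components and held-out AUC), `holdout` (edge
#'   matrix used for monitoring), `config`.
#' @export
fit_vgae <- function(X, graph, config = training_config()) {
  if (inherits(X, "sc_expr")) X <- X$values
  X <- as.matrix(X)
  stopifnot(inherits(graph, "cell_graph"))
  if (nrow(X) != graph$n_nodes) {
    stop("feature rows must match the number of graph nodes")
  }
  if (nrow(graph$edges) < 1) stop("graph has no edges to reconstruct")
  seed <- config$seed

  split <- holdout_split(graph, config$holdout_fraction, seed = seed + 11L)
  train_graph <- split$train
  held_pos <- split$holdout
  held_neg <- if (nrow(held_pos)) {
    sample_negative_edges(graph, nrow(held_pos), seed = seed + 13L)
  } else matrix(integer(), ncol = 2)

  model <- vgae_init(ncol(X), hidden_dims = config$hidden_dims,
                     latent_dim = config$latent_dim,
                     n_heads = config$n_heads,
                     use_feature_recon = config$use_feature_recon,
                     seed = seed)
  params <- model_params(model)
  state <- adam_init(params)
  pos <- train_graph$edges
  n_lat <- config$latent_dim
  reg_weight <- config$reg_weight
  if (is.null(reg_weight)) {
    reg_weight <- if (config$reg_kind == "kl") 1 / graph$n_nodes else 1
  }

  hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                     reg = NA_real_, recon = NA_real_,
                     feature_recon = NA_real_, holdout_auc = NA_real_)
  attn <- NULL
  for (epoch in seq_len(config$epochs)) {
    neg <- sample_negative_edges(train_graph, nrow(pos),
                                 seed = seed + 100000L + epoch)
    epsilon <- with_local_seed(seed + 200000L + epoch, {
      matrix(stats::rnorm(graph$n_nodes * n_lat), graph$n_nodes, n_lat)
    })
    prior <- NULL
    if (config$reg_kind == "mmd") {
      prior <- with_local_seed(seed + 300000L + epoch, {
        matrix(stats::rnorm(graph$n_nodes * n_lat), graph$n_nodes, n_lat)
      })
    }
    step <- vgae_loss_and_grads(model, X, train_graph, pos, neg, epsilon,
                                reg_kind = config$reg_kind,
                                prior_samples = prior,
                                mmd_bandwidth = config$mmd_bandwidth,
                                use_feature_recon = config$use_feature_recon,
                                reg_weight = reg_weight)
    if (!is.finite(step$loss)) {
      stop(sprintf("training diverged at epoch %d (loss = %s); try a lower learning rate",
                   epoch, format(step$loss)))
    }
    upd <- adam_step(params, step$grads, state, lr = config$learning_rate)
    params <- upd$params
    state <- upd$state
    model <- set_model_params(model, params)
    hist$loss[epoch] <- step$loss
    hist$reg[epoch] <- step$components$reg
    hist$recon[epoch] <- step$components$recon
    hist$feature_recon[epoch] <- if (is.null(step$components$feature_recon)) NA_real_ else step$components$feature_recon
    if (nrow(held_pos)) {
      hist$holdout_auc[epoch] <- edge_auc(step$mu, held_pos, held_neg)
    }
    attn <- step$attention
  }
  enc <- vgae_encode(model, X, graph)
  structure(list(model = model, embedding = enc$mu,
                 attention = enc$attention, history = hist,
                 holdout = held_pos, holdout_negatives = held_neg,
                 config = config),
            class = "vgae_fit")
}

#' @method print vgae_fit
#' @export
print.vgae_fit <- function(x, ...) {
  cat(sprintf("<vgae_fit> %d cells -> %d latent dims | %d epochs, final loss %.4f\n",
              nrow(x$embedding), ncol(x$embedding), nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' ROC-AUC of the inner-product decoder on labelled edge sets
#'
#' @param Z latent matrix.
#' @param pos_edges,neg_edges two-column edge matrices (true edges /
#'   non-edges).
#' @return AUC in `[0, 1]`.
#' @export
edge_auc <- function(Z, pos_edges, neg_edges) {
  scores <- c(decode_edges(Z, pos_edges), decode_edges(Z, neg_edges))
  labels <- c(rep(1L, nrow(pos_edges)), rep(0L, nrow(neg_edges)))
  as.numeric(pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                       quiet = TRUE)$auc)
}
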