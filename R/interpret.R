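#' Per-node attention overlay
#'
#' Collapses an attention record to one scalar per node for use as a colour
#' overlay on 2-D projections. For `direction = "incoming"` (default) the
#' value of node v is the mean of the coefficients with which *other* nodes
#' attend to v — high values mark cells whose features contribute most to
#' the rest of the model. `"outgoing"` averages the coefficients v assigns
#' over its own neighbourhood. Heads (and layers, if several are present in
#' the record) are pooled by averaging.
#'
#' @param attn an `attention_record` (columns layer, head, src, dst,
#'   alpha).
#' @param direction `"incoming"` or `"outgoing"`.
#' @param layer optional layer id filter.
#' @param head optional head id filter (default: mean across heads).
#' @return Named numeric vector indexed by node; nodes absent from the
#'   record in the chosen direction get `NA`.
#' @export
node_attention_overlay <- function(attn, direction = c("incoming", "outgoing"),
                                   layer = NULL, head = NULL) {
  direction <- match.arg(direction)
  a <- as.data.frame(attn)
  if (!is.null(layer)) a <- a[a$layer %in% layer, ]
  if (!is.null(head)) a <- a[a$head %in% head, ]
  if (!nrow(a)) stop("attention record is empty after filtering")
  key <- if (direction == "incoming") a$dst else a$src
  means <- tapply(a$alpha, key, mean)
  nodes <- max(a$src, a$dst)
  out <- rep(NA_real_, nodes)
  out[as.integer(names(means))] <- as.numeric(means)
  names(out) <- seq_len(nodes)
  out
}

#' Top-n attention edges as a weighted directed graph
#'
#' Selects the `n` largest attention coefficients as directed weighted
#' edges. Coefficients are direction-specific (`alpha_ij != alpha_ji`), so
#' the result is a directed graph. Ties are broken lexicographically by
#' (layer, head, src, dst). Optionally restricts to a coefficient range or
#' excludes nodes (e.g. particular cell types).
#'
#' @param attn an `attention_record`.
#' @param n number of edges to keep.
#' @param exclude_nodes optional node indices to drop (as src or dst).
#' @param min_alpha,max_alpha optional coefficient range filter.
#' @return The top rows of the record, ordered by decreasing `alpha`.
#' @export
top_attention_edges <- function(attn, n, exclude_nodes = NULL,
                                min_alpha = NULL, max_alpha = NULL) {
  stopifnot(n >= 1)
  a <- as.data.frame(attn)
  if (!is.null(exclude_nodes)) {
    a <- a[!(a$src %in% exclude_nodes | a$dst %in% exclude_nodes), ]
  }
  if (!is.null(min_alpha)) a <- a[a$alpha >= min_alpha, ]
  if (!is.null(max_alpha)) a <- a[a$alpha <= max_alpha, ]
  if (n > nrow(a)) {
    warning(sprintf("requested %d edges but only %d coefficients available; returning all",
                    n, nrow(a)))
    n <- nrow(a)
  }
  ord <- order(-a$alpha, a$layer, a$head, a$src, a$dst)
  out <- a[ord[seq_len(n)], ]
  rownames(out) <- NULL
  class(out) <- c("attention_record", "data.frame")
  out
}

#' Latent distances of the top-attending cell pairs
#'
#' For the `top_n` largest attention coefficients, computes the Euclidean
#' distance between the two cells in the latent embedding. Large distances
#' for high-attention pairs indicate that attention carries information not
#' already present in latent proximity.
#'
#' @param attn an `attention_record`.
#' @param Z latent embedding whose rows cover the record's nodes.
#' @param top_n number of pairs to examine.
#' @return Data frame with `rank`, `src`, `dst`, `alpha`, `distance`,
#'   ordered by decreasing coefficient.
#' @export
attention_vs_latent_distance <- function(attn, Z, top_n = 80) {
  Z <- as.matrix(Z)
  top <- top_attention_edges(attn, top_n)
  dist <- sqrt(rowSums((Z[top$src, , drop = FALSE] -
                        Z[top$dst, , drop = FALSE])^2))
  data.frame(rank = seq_len(nrow(top)), src = top$src, dst = top$dst,
             alpha = top$alpha, distance = dist)
}

#' Encoder weight products linking genes to latent dimensions
#'
#' Chains the transposed per-layer weight matrices of the encoder:
#' `P_mu = W_1' . W_2' ... W_mu'` (and analogously `P_sigma`), giving
#' `D x L` matrices whose entry (g, l) scores how strongly input gene g
#' loads on latent dimension l through the linear part of the attention
#' layers. Inner-layer matrices are the per-head blocks stacked to the
#' `K * D_i` concatenated width; the head-averaging output layers
#' contribute the mean of their head matrices.
#'
#' @param W1,W2 inner-layer weight matrices (`K*D_i x D_in` stacked form).
#'   `W2` may be `NULL` for a single-inner-layer model.
#' @param W_mu,W_sigma output-layer weight matrices (`L x width`).
#' @return A `weight_products` list with `P_mu` and `P_sigma` (`D x L`).
#' @export
weight_products <- function(W1, W2, W_mu, W_sigma) {
  mats <- Filter(Negate(is.null), list(W1, W2))
  chain <- function(out_w) {
    acc <- NULL
    for (m in mats) {
      m <- as.matrix(m)
      acc <- if (is.null(acc)) t(m) else {
        if (ncol(acc) != ncol(m)) stop("weight chain dimensions do not compose")
        acc %*% t(m)
      }
    }
    out_w <- as.matrix(out_w)
    if (ncol(acc) != ncol(out_w)) stop("weight chain dimensions do not compose")
    acc %*% t(out_w)
  }
  structure(list(P_mu = chain(W_mu), P_sigma = chain(W_sigma)),
            class = "weight_products")
}

#' Weight products of a trained model
#'
#' Assembles the stacked/averaged weight matrices from a `vgae_model` (any
#' number of inner layers) and chains them with [weight_products()].
#'
#' @param model a `vgae_model` (or `vgae_fit`).
#' @return A `weight_products` list with `P_mu`, `P_sigma`.
#' @export
model_weight_products <- function(model) {
  if (inherits(model, "vgae_fit")) model <- model$model
  stopifnot(inherits(model, "vgae_model"))
  stack_heads <- function(layer) do.call(rbind, lapply(layer$heads, `[[`, "W"))
  mean_heads <- function(layer) Reduce(`+`, lapply(layer$heads, `[[`, "W")) / layer$n_heads
  acc <- NULL
  for (layer in model$inner) {
    m <- stack_heads(layer)
    acc <- if (is.null(acc)) t(m) else acc %*% t(m)
  }
  structure(list(P_mu = acc %*% t(mean_heads(model$mu_layer)),
                 P_sigma = acc %*% t(mean_heads(model$sigma_layer))),
            class = "weight_products")
}

#' Rank marker genes per cluster from the weight products
#'
#' For each cluster: latent dimensions are ranked by the mean absolute
#' embedding value of the cluster's cells and the `n_top_dims` most active
#' dimensions are kept — restricting to a few leading dimensions is what
#' makes the report cluster-specific, since the per-dimension gene lists
#' themselves do not depend on the cluster. For every kept dimension, the
#' `top_per_dim` genes with the largest `|P_mu|` column weights are
#' collected, and each gene's number of appearances across dimensions is
#' accumulated. The per-cluster report lists genes in descending appearance
#' count. Genes appearing only once but lying within the `top_weight_pool`
#' largest `|P_mu|` entries overall are reported as a secondary list.
#'
#' @param P_mu `D x L` weight-product matrix (or a `weight_products`).
#' @param embedding `N x L` latent embedding.
#' @param assignment a `cluster_assignment` or label vector (`-1` noise).
#' @param top_per_dim genes taken per latent dimension (default 15).
#' @param n_top_dims latent dimensions used per cluster (default 3;
#'   `NULL` = all dimensions, in relevance order).
#' @param top_weight_pool size of the global high-weight pool used for the
#'   secondary list (default 100).
#' @param gene_ids optional gene identifiers (default `gene_<index>`).
#' @return A `gene_report` list with one element per cluster, each holding
#'   `primary` (data frame: gene, appearances, max_weight) and `secondary`
#'   (genes appearing once but in the global top-weight pool).
#' @export
ranked_genes <- function(P_mu, embedding, assignment, top_per_dim = 15,
                         n_top_dims = 3, top_weight_pool = 100,
                         gene_ids = NULL) {
  if (inherits(P_mu, "weight_products")) P_mu <- P_mu$P_mu
  P_mu <- as.matrix(P_mu)
  embedding <- as.matrix(embedding)
  labels <- if (inherits(assignment, "cluster_assignment")) assignment$labels else as.integer(assignment)
  if (nrow(embedding) != length(labels)) {
    stop("cluster labels do not match embedding rows")
  }
  if (ncol(P_mu) != ncol(embedding)) {
    stop("P_mu latent width does not match embedding width")
  }
  d <- nrow(P_mu)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(d))
  top_per_dim <- min(top_per_dim, d)
  absP <- abs(P_mu)
  # genes per dimension, by decreasing |weight|, ties to lower gene index
  genes_by_dim <- lapply(seq_len(ncol(P_mu)), function(l) {
    order(-absP[, l], seq_len(d))[seq_len(top_per_dim)]
  })
  # global pool: the top_weight_pool largest entries of |P_mu|
  pool_n <- min(top_weight_pool, length(absP))
  flat_ord <- order(-as.vector(absP), seq_along(absP))[seq_len(pool_n)]
  pool_genes <- unique(((flat_ord - 1) %% d) + 1)

  clusters <- sort(unique(labels[labels != -1L]))
  report <- lapply(clusters, function(cl) {
    cells <- which(labels == cl)
    relevance <- colMeans(abs(embedding[cells, , drop = FALSE]))
    dim_order <- order(-relevance, seq_along(relevance))
    n_dims <- if (is.null(n_top_dims)) length(dim_order) else min(n_top_dims, length(dim_order))
    dim_order <- dim_order[seq_len(n_dims)]
    picked <- unlist(genes_by_dim[dim_order])
    counts <- table(factor(picked, levels = seq_len(d)))
    counts <- counts[counts > 0]
    gidx <- as.integer(names(counts))
    maxw <- vapply(gidx, function(g) max(absP[g, ]), numeric(1))
    ord <- order(-as.integer(counts), gidx)
    primary <- data.frame(
      gene = gene_ids[gidx[ord]],
      gene_index = gidx[ord],
      appearances = as.integer(counts)[ord],
      max_weight = maxw[ord],
      stringsAsFactors = FALSE
    )
    once <- gidx[as.integer(counts) == 1]
    secondary <- intersect(once, pool_genes)
    list(cluster = cl, primary = primary,
         secondary = gene_ids[secondary],
         dim_order = dim_order)
  })
  names(report) <- paste0("cluster_", clusters)
  structure(report, class = "gene_report")
}

#' Write a gene report as TSV
#'
#' Columns: cluster, rank, gene_id, appearance_count, max_weight, source
#' (`latent` for the per-dimension ranking, `top_pool` for the secondary
#' high-weight list).
#'
#' @param report a `gene_report` from [ranked_genes()].
#' @param path output file path.
#' @param header optional `#`-prefixed comment line.
#' @return Invisibly, `path`.
#' @export
write_gene_report <- function(report, path, header = NULL) {
  rows <- list()
  for (entry in report) {
    p <- entry$primary
    if (nrow(p)) {
      rows[[length(rows) + 1]] <- data.frame(
        cluster = entry$cluster, rank = seq_len(nrow(p)), gene_id = p$gene,
        appearance_count = p$appearances, max_weight = p$max_weight,
        source = "latent", stringsAsFactors = FALSE)
    }
    if (length(entry$secondary)) {
      rows[[length(rows) + 1]] <- data.frame(
        cluster = entry$cluster, rank = seq_along(entry$secondary),
        gene_id = entry$secondary, appearance_count = 1L,
        max_weight = NA_real_, source = "top_pool", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {  # no clusters found: header-only report
    out <- data.frame(cluster = integer(), rank = integer(),
                      gene_id = character(), appearance_count = integer(),
                      max_weight = numeric(), source = character())
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Learnt per-cell expression score for one gene
#'
#' Projects the latent embedding onto a gene's loading vector: with
#' `g = P_mu[gene, ]`, returns `E . g`, one scalar per cell. Positive
#' values read as learnt high expression, negative as the opposite; the
#' sign is preserved and no rescaling is applied.
#'
#' @param embedding `N x L` latent embedding.
#' @param P_mu `D x L` weight products (or a `weight_products`).
#' @param gene_index gene row index in `P_mu`.
#' @return Numeric vector of length N.
#' @export
learnt_gene_expression <- function(embedding, P_mu, gene_index) {
  if (inherits(P_mu, "weight_products")) P_mu <- P_mu$P_mu
  P_mu <- as.matrix(P_mu)
  embedding <- as.matrix(embedding)
  if (gene_index < 1 || gene_index > nrow(P_mu)) {
    stop(sprintf("gene_index %d out of range [1, %d]", gene_index, nrow(P_mu)))
  }
  drop(embedding %*% P_mu[gene_index, ])
}
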