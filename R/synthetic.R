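#' Generate clustered single-cell-like count data
#'
#' Seeded negative-binomial count simulator with planted cluster structure.
#' Every gene gets a base mean drawn log-normally (median 1, so most genes
#' are lowly expressed); each cluster receives a disjoint block of marker
#' genes whose mean is multiplied by `fold_change` in that cluster only.
#' Counts are drawn from a negative binomial with the given dispersion
#' (variance `mu + dispersion * mu^2`), the community-standard count model
#' for single-cell RNA-seq. Cluster sizes are balanced unless explicit
#' `proportions` are given (imbalance supports testing small-cluster
#' rescue).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_clusters number of planted clusters (>= 1).
#' @param markers_per_cluster marker genes per cluster (disjoint blocks;
#'   must fit in `n_genes`).
#' @param fold_change marker mean multiplier inside the owning cluster; 1
#'   plants no structure.
#' @param dispersion negative-binomial dispersion (1 / size); 0 gives
#'   Poisson counts.
#' @param base_mean_log_sd spread of the log-normal gene base means.
#' @param mean_scale multiplier applied to all base means (sequencing
#'   depth).
#' @param proportions optional cluster proportions (length `n_clusters`,
#'   summing to 1).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A `synthetic_dataset`: list with `counts` (an `sc_expr`),
#'   `true_labels` (0-based cluster per cell), `marker_map` (list of marker
#'   gene indices per cluster), `seed`.
#' @export
generate_counts <- function(n_cells = 300, n_genes = 500, n_clusters = 3,
                            markers_per_cluster = 10, fold_change = 8,
                            dispersion = 0.3, base_mean_log_sd = 0.4,
                            mean_scale = 8, proportions = NULL, seed = 1L) {
  stopifnot(n_clusters >= 1, n_cells >= n_clusters)
  if (n_clusters * markers_per_cluster > n_genes) {
    stop("marker allocation infeasible: n_clusters * markers_per_cluster exceeds n_genes")
  }
  if (is.null(proportions)) {
    proportions <- rep(1 / n_clusters, n_clusters)
  }
  if (length(proportions) != n_clusters || abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must have length n_clusters and sum to 1")
  }
  sizes <- floor(proportions * n_cells)
  while (sum(sizes) < n_cells) {
    sizes[which.max(proportions * n_cells - sizes)] <- sizes[which.max(proportions * n_cells - sizes)] + 1
  }
  if (any(sizes < 1)) stop("a cluster received no cells; adjust proportions")
  labels <- rep(seq_len(n_clusters) - 1L, times = sizes)
  marker_map <- lapply(seq_len(n_clusters), function(c0) {
    ((c0 - 1) * markers_per_cluster + 1):((c0 - 1) * markers_per_cluster + markers_per_cluster)
  })
  names(marker_map) <- paste0("cluster_", seq_len(n_clusters) - 1L)

  counts <- with_local_seed(seed, {
    base_mean <- stats::rlnorm(n_genes, meanlog = 0, sdlog = base_mean_log_sd) * mean_scale
    m <- matrix(0L, n_cells, n_genes)
    for (c0 in seq_len(n_clusters)) {
      cells <- which(labels == c0 - 1L)
      mu <- base_mean
      mu[marker_map[[c0]]] <- mu[marker_map[[c0]]] * fold_change
      draw <- if (dispersion > 0) {
        stats::rnbinom(length(cells) * n_genes, mu = rep(mu, each = length(cells)),
                       size = 1 / dispersion)
      } else {
        stats::rpois(length(cells) * n_genes, lambda = rep(mu, each = length(cells)))
      }
      m[cells, ] <- matrix(draw, length(cells), n_genes)
    }
    # guard the log-normalization precondition: no all-zero cells
    zero_cells <- rowSums(m) == 0
    if (any(zero_cells)) m[zero_cells, 1] <- 1L
    m
  })
  expr <- expression_matrix(counts)
  structure(list(counts = expr, true_labels = labels,
                 marker_map = marker_map, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @method print synthetic_dataset
#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d cells x %d genes, %d clusters (seed %d)\n",
              nrow(x$counts$values), ncol(x$counts$values),
              length(x$marker_map), x$seed))
  invisible(x)
}

#' Generate a stochastic-block-model cell graph
#'
#' Simple undirected graph with planted block (community) structure:
#' within-block edges appear with probability `p_in`, between-block edges
#' with `p_out`. Used as a link-prediction fixture with known ground truth.
#'
#' @param n_nodes number of nodes.
#' @param n_blocks number of blocks (balanced sizes).
#' @param p_in,p_out within-/between-block edge probabilities
#'   (`0 <= p_out <= p_in <= 1`).
#' @param seed integer seed.
#' @return List with `graph` (a `cell_graph`) and `labels` (0-based block
#'   id per node).
#' @export
generate_block_graph <- function(n_nodes, n_blocks = 2, p_in = 0.5,
                                 p_out = 0.05, seed = 1L) {
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1 || p_out > p_in) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  sizes <- rep(n_nodes %/% n_blocks, n_blocks)
  rem <- n_nodes - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  pref <- matrix(p_out, n_blocks, n_blocks)
  diag(pref) <- p_in
  g <- with_local_seed(seed, {
    igraph::sample_sbm(n_nodes, pref.matrix = pref, block.sizes = sizes,
                       directed = FALSE, loops = FALSE)
  })
  e <- igraph::as_edgelist(g, names = FALSE)
  labels <- rep(seq_len(n_blocks) - 1L, times = sizes)
  list(graph = cell_graph(n_nodes, e), labels = labels)
}
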