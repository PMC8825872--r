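#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same cells,
#' computed from the pair counts of the contingency table:
#' `ARI = (Index - Expected) / (Max - Expected)`. 1 for identical
#' partitions, approximately 0 for independent ones; can be negative.
#'
#' Noise labels (`-1`) can be dropped (cells unassigned by either labelling
#' are excluded — the convention used when comparing density-based
#' clusterings to a reference, since unassigned cells are reported
#' separately), kept as-is (`-1` treated as one shared label), or turned
#' into per-cell singleton clusters.
#'
#' @param labels_a,labels_b integer/character label vectors of equal
#'   length; `-1` (or `"-1"`) marks noise.
#' @param noise one of `"drop"` (default), `"singleton"`, `"keep"`.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b,
                                noise = c("drop", "singleton", "keep")) {
  noise <- match.arg(noise)
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  a <- as.vector(labels_a); b <- as.vector(labels_b)
  is_noise_a <- a == -1; is_noise_b <- b == -1
  if (noise == "drop") {
    keep <- !(is_noise_a | is_noise_b)
    a <- a[keep]; b <- b[keep]
    if (!length(a)) stop("no cells left after dropping noise")
  } else if (noise == "singleton") {
    n <- length(a)
    a <- ifelse(is_noise_a, paste0(".noise", seq_len(n)), as.character(a))
    b <- ifelse(is_noise_b, paste0(".noise", seq_len(n)), as.character(b))
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Mean silhouette coefficient of a clustering
#'
#' For each cell, `s = (b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to its own cluster and `b` the smallest mean distance to any
#' other cluster; the coefficient is the mean of `s` over cells. Noise
#' cells (`-1`) are excluded. Requires at least two non-noise clusters.
#'
#' @param Z numeric matrix of coordinates (e.g. the latent embedding).
#' @param labels integer labels, `-1` for noise.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_coefficient <- function(Z, labels) {
  Z <- as.matrix(Z)
  labels <- as.integer(labels)
  stopifnot(nrow(Z) == length(labels))
  keep <- labels != -1L
  Zk <- Z[keep, , drop = FALSE]
  lk <- labels[keep]
  if (length(unique(lk)) < 2) {
    stop("silhouette requires at least 2 non-noise clusters")
  }
  sil <- cluster::silhouette(lk, stats::dist(Zk))
  mean(sil[, "sil_width"])
}

#' Overlap percentage between a found cluster and a reference cluster
#'
#' `100 * |found intersect reference| / |reference|` — the fraction of the
#' reference cluster's cells recovered by the found cluster.
#'
#' @param found_cluster,reference_cluster vectors of cell identifiers (any
#'   atomic type); the reference must be non-empty.
#' @return Percentage in `[0, 100]`.
#' @export
cluster_overlap_percent <- function(found_cluster, reference_cluster) {
  if (!length(reference_cluster)) stop("reference cluster must be non-empty")
  100 * length(intersect(found_cluster, reference_cluster)) /
    length(unique(reference_cluster))
}

#' Match found clusters to reference labels by maximal overlap
#'
#' Each found cluster is mapped to the reference label sharing the most
#' cells with it; ties go to the smaller reference label. Noise cells are
#' ignored on both sides.
#'
#' @param assignment a `cluster_assignment` or an integer label vector.
#' @param reference_labels vector of reference labels, same length.
#' @return Named vector: names are found cluster labels, values the matched
#'   reference labels.
#' @export
match_clusters_to_reference <- function(assignment, reference_labels) {
  labels <- if (inherits(assignment, "cluster_assignment")) assignment$labels else as.integer(assignment)
  if (length(labels) != length(reference_labels)) {
    stop("label vectors must have equal length")
  }
  found_ids <- sort(unique(labels[labels != -1L]))
  out <- vapply(found_ids, function(fc) {
    cells <- which(labels == fc)
    refs <- reference_labels[cells]
    refs <- refs[refs != -1]
    if (!length(refs)) return(NA_integer_)
    counts <- table(refs)
    best <- max(counts)
    cand <- names(counts)[counts == best]
    # ties to the smaller reference label
    as.integer(sort(cand)[1])
  }, integer(1))
  names(out) <- found_ids
  out
}

#' Summarize clustering quality against reference labels
#'
#' Convenience wrapper computing the adjusted Rand index, the silhouette
#' coefficient on the embedding, the noise count and the cluster count.
#'
#' @param Z latent embedding.
#' @param assignment a `cluster_assignment`.
#' @param reference_labels ground-truth/reference labels.
#' @param noise noise handling for the ARI (see
#'   [adjusted_rand_index()]).
#' @return Named list `ari`, `sc`, `n_noise`, `n_clusters`.
#' @export
clustering_metrics <- function(Z, assignment, reference_labels,
                               noise = "drop") {
  labels <- assignment$labels
  ari <- adjusted_rand_index(labels, reference_labels, noise = noise)
  sc <- tryCatch(silhouette_coefficient(Z, labels), error = function(e) NA_real_)
  list(ari = ari, sc = sc, n_noise = assignment$n_noise,
       n_clusters = assignment$n_clusters)
}
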