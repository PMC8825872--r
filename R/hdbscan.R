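# Hierarchical density-based clustering (HDBSCAN), implemented natively:
# mutual-reachability distances -> minimum spanning tree -> single-linkage
# hierarchy -> condensed tree (minimum cluster size) -> excess-of-mass
# cluster selection. Points that never join a selected cluster are noise
# (label -1); cluster labels are contiguous from 0, matching the convention
# of the reference implementations so results are directly comparable.

#' Density-based clustering of a point set
#'
#' @param X numeric matrix of points (rows) in Euclidean space.
#' @param min_cluster_size smallest group treated as a cluster (>= 2).
#' @param min_samples neighbour count for core distances (defaults to
#'   `min_cluster_size`); larger values smooth the density estimate.
#' @param allow_single_cluster permit the hierarchy root to be returned as
#'   a single cluster; off by default, matching standard practice.
#' @return Integer vector of labels: `-1` for noise, clusters numbered from
#'   0.
#' @export
hdbscan_labels <- function(X, min_cluster_size = 5,
                           min_samples = min_cluster_size,
                           allow_single_cluster = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (min_cluster_size < 2) stop("min_cluster_size must be at least 2")
  if (n < 2) return(rep(0L, n))
  d <- as.matrix(stats::dist(X))
  if (max(d) == 0) return(rep(0L, n))  # all points identical: one cluster
  ms <- min(min_samples, n)
  core <- apply(d, 1, function(r) sort(r)[ms])  # self counts as 1st neighbour
  mreach <- pmax(d, outer(core, core, pmax))
  mst <- prim_mst(mreach)
  slt <- single_linkage_tree(mst, n)
  cond <- condense_tree(slt, n, min_cluster_size)
  select_and_label(cond, n, allow_single_cluster)
}

# Prim's algorithm on a dense distance matrix; returns (i, j, weight) rows
prim_mst <- function(d) {
  n <- nrow(d)
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best <- d[1, ]
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    edges[step, ] <- c(best_from[v], v, best[v])
    in_tree[v] <- TRUE
    improved <- !in_tree & d[v, ] < best
    best[improved] <- d[v, improved]
    best_from[improved] <- v
  }
  edges
}

# Single-linkage hierarchy from sorted MST edges, union-find based.
# Nodes 1..n are leaves; merge nodes n+1 .. 2n-1 store children, height
# (merge distance) and subtree size.
single_linkage_tree <- function(mst, n) {
  ord <- order(mst[, 3])
  mst <- mst[ord, , drop = FALSE]
  parent <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  comp_node <- seq_len(n)         # component representative -> dendrogram node
  left <- integer(n - 1); right <- integer(n - 1)
  height <- numeric(n - 1); size <- integer(2L * n - 1L)
  size[seq_len(n)] <- 1L
  nxt <- n
  for (r in seq_len(nrow(mst))) {
    a <- find(mst[r, 1]); b <- find(mst[r, 2])
    nxt <- nxt + 1L
    idx <- nxt - n
    left[idx] <- comp_node[a]; right[idx] <- comp_node[b]
    height[idx] <- mst[r, 3]
    size[nxt] <- size[comp_node[a]] + size[comp_node[b]]
    parent[a] <- b
    comp_node[b] <- nxt
  }
  list(left = left, right = right, height = height, size = size, n = n)
}

# Leaf points under a dendrogram node (iterative to avoid deep recursion)
leaves_under <- function(slt, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= slt$n) out <- c(out, v)
    else {
      idx <- v - slt$n
      stack <- c(stack, slt$left[idx], slt$right[idx])
    }
  }
  out
}

# Condense the single-linkage tree: clusters persist while they keep at
# least min_cluster_size points; smaller split-offs "fall out" as points at
# the split's lambda = 1/distance.
condense_tree <- function(slt, n, mcs) {
  finite_h <- slt$height[slt$height > 0]
  lam_cap <- if (length(finite_h)) 1 / min(finite_h) * 1e6 else 1
  lam <- function(h) if (h > 0) 1 / h else lam_cap

  cl_parent <- 0            # root cluster has no parent
  cl_birth <- 0             # root born at lambda 0
  n_clusters <- 1L
  point_cluster <- integer(n)
  point_lambda <- numeric(n)
  child_parent <- integer(0)  # cluster split bookkeeping for stability
  child_id <- integer(0)
  child_lambda <- numeric(0)
  child_size <- integer(0)

  root <- 2L * n - 1L
  # stack entries: (slt node, condensed cluster it currently belongs to)
  stack_node <- root
  stack_cl <- 1L
  while (length(stack_node)) {
    v <- stack_node[length(stack_node)]
    cl <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    repeat {
      if (v <= n) { # singleton reached while descending: falls out at cap
        point_cluster[v] <- cl
        point_lambda[v] <- lam_cap
        break
      }
      idx <- v - n
      l <- slt$left[idx]; r <- slt$right[idx]
      sl <- slt$size[l]; sr <- slt$size[r]
      lv <- lam(slt$height[idx])
      if (sl >= mcs && sr >= mcs) {
        for (ch in c(l, r)) {
          n_clusters <- n_clusters + 1L
          cl_parent[n_clusters] <- cl
          cl_birth[n_clusters] <- lv
          child_parent <- c(child_parent, cl)
          child_id <- c(child_id, n_clusters)
          child_lambda <- c(child_lambda, lv)
          child_size <- c(child_size, slt$size[ch])
          stack_node <- c(stack_node, ch)
          stack_cl <- c(stack_cl, n_clusters)
        }
        break
      } else if (sl < mcs && sr < mcs) {
        for (p in leaves_under(slt, v)) {
          point_cluster[p] <- cl
          point_lambda[p] <- lv
        }
        break
      } else {
        small <- if (sl < mcs) l else r
        big <- if (sl < mcs) r else l
        for (p in leaves_under(slt, small)) {
          point_cluster[p] <- cl
          point_lambda[p] <- lv
        }
        v <- big  # keep descending inside the same condensed cluster
      }
    }
  }

  stability <- numeric(n_clusters)
  for (p in seq_len(n)) {
    c0 <- point_cluster[p]
    stability[c0] <- stability[c0] + (point_lambda[p] - cl_birth[c0])
  }
  for (i in seq_along(child_parent)) {
    c0 <- child_parent[i]
    stability[c0] <- stability[c0] +
      child_size[i] * (child_lambda[i] - cl_birth[c0])
  }
  list(n_clusters = n_clusters, parent = cl_parent, birth = cl_birth,
       stability = stability, point_cluster = point_cluster,
       point_lambda = point_lambda)
}

# Excess-of-mass cluster selection and final labelling
select_and_label <- function(cond, n, allow_single_cluster) {
  k <- cond$n_clusters
  children <- vector("list", k)
  for (c0 in seq_len(k)[-1]) {
    p <- cond$parent[c0]
    children[[p]] <- c(children[[p]], c0)
  }
  selected <- logical(k)
  score <- numeric(k)
  lowest <- if (allow_single_cluster) 1L else 2L
  for (c0 in rev(seq_len(k))) {           # children have larger ids
    ch <- children[[c0]]
    if (c0 < lowest) { score[c0] <- sum(score[ch]); next }
    if (!length(ch)) {
      selected[c0] <- TRUE
      score[c0] <- cond$stability[c0]
    } else {
      child_sum <- sum(score[ch])
      if (cond$stability[c0] >= child_sum) {
        selected[c0] <- TRUE
        score[c0] <- cond$stability[c0]
        # deselect every descendant
        stack <- ch
        while (length(stack)) {
          v <- stack[length(stack)]; stack <- stack[-length(stack)]
          selected[v] <- FALSE
          stack <- c(stack, children[[v]])
        }
      } else {
        score[c0] <- child_sum
      }
    }
  }
  sel_ids <- which(selected)
  labels <- rep(-1L, n)
  if (length(sel_ids)) {
    relabel <- integer(k)
    relabel[sel_ids] <- seq_along(sel_ids) - 1L
    for (p in seq_len(n)) {
      c0 <- cond$point_cluster[p]
      while (c0 != 0L && !selected[c0]) c0 <- cond$parent[c0]
      if (c0 != 0L) labels[p] <- relabel[c0]
    }
  }
  labels
}

#' Cluster a latent embedding with HDBSCAN
#'
#' Runs density-based clustering on the per-cell latent coordinates (the
#' posterior means of the trained autoencoder). Cells in regions of
#' insufficient density are labelled noise (`-1`) and counted.
#'
#' @param Z numeric matrix of latent coordinates, one row per cell.
#' @param min_cluster_size smallest cell group accepted as a cluster;
#'   default `max(5, 0.5%` of cells`)`.
#' @param min_samples see [hdbscan_labels()].
#' @return A `cluster_assignment`: list with `labels` (integer per cell,
#'   `-1` = noise), `n_noise`, `n_clusters`, `min_cluster_size`.
#' @export
cluster_latent <- function(Z, min_cluster_size = NULL, min_samples = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (is.null(min_cluster_size)) min_cluster_size <- max(5, ceiling(0.005 * n))
  if (n < min_cluster_size) {
    stop(sprintf("need at least min_cluster_size (%d) rows; got %d",
                 min_cluster_size, n))
  }
  if (is.null(min_samples)) min_samples <- min_cluster_size
  labels <- hdbscan_labels(Z, min_cluster_size = min_cluster_size,
                           min_samples = min_samples)
  cluster_assignment(labels, min_cluster_size = min_cluster_size)
}

#' Construct a cluster assignment object
#'
#' @param labels integer labels, `-1` for noise; non-noise labels are
#'   re-coded to be contiguous from 0.
#' @param min_cluster_size bookkeeping field (optional).
#' @return A `cluster_assignment` list.
#' @export
cluster_assignment <- function(labels, min_cluster_size = NA) {
  labels <- as.integer(labels)
  pos <- sort(unique(labels[labels >= 0]))
  if (length(pos)) {
    labels[labels >= 0] <- match(labels[labels >= 0], pos) - 1L
  }
  structure(list(labels = labels, n_noise = sum(labels == -1L),
                 n_clusters = length(pos),
                 min_cluster_size = min_cluster_size),
            class = "cluster_assignment")
}

#' @method print cluster_assignment
#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cells: %d clusters, %d noise\n",
              length(x$labels), x$n_clusters, x$n_noise))
  invisible(x)
}

#' Rescue very small clusters from the noise set
#'
#' Post-processing so that clusters below the main `min_cluster_size` are
#' not lost: density clustering is re-run on the noise points only, with the
#' reduced minimum size `rescue_min_size`; any groups found become new
#' clusters. Existing cluster memberships are never modified, so the number
#' of clusters can only grow.
#'
#' @param assignment a `cluster_assignment` from [cluster_latent()].
#' @param Z the latent matrix the assignment was computed on.
#' @param rescue_min_size minimum size for rescued clusters (>= 2).
#' @return An updated `cluster_assignment`.
#' @export
rescue_small_clusters <- function(assignment, Z, rescue_min_size = 3) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  Z <- as.matrix(Z)
  labels <- assignment$labels
  noise_idx <- which(labels == -1L)
  if (length(noise_idx) < rescue_min_size) return(assignment)
  sub <- hdbscan_labels(Z[noise_idx, , drop = FALSE],
                        min_cluster_size = rescue_min_size)
  found <- sub >= 0
  if (any(found)) {
    offset <- assignment$n_clusters
    labels[noise_idx[found]] <- sub[found] + offset
  }
  cluster_assignment(labels, min_cluster_size = assignment$min_cluster_size)
}
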