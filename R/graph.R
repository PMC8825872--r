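#' Construct a cell graph
#'
#' A simple undirected graph over cells: no self-loops, no duplicate edges,
#' symmetric by construction. Node indices are 1-based internally (standard
#' R indexing); edge-list files use 0-based indices at the I/O boundary.
#'
#' @param n_nodes number of nodes (cells).
#' @param edges two-column integer matrix of 1-based node pairs; may be
#'   empty. Self-loops and duplicates are rejected here (use
#'   [read_edge_list()] for tolerant parsing of external files).
#' @return An object of class `cell_graph` with elements `n_nodes` and
#'   `edges` (two-column matrix, each row `i < j`, rows sorted).
#' @export
cell_graph <- function(n_nodes, edges = matrix(integer(), ncol = 2)) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1, n_nodes >= 0)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n_nodes)) {
      stop("edge indices out of range [1, n_nodes]")
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- canonical_edges(edges)
    if (anyDuplicated(edges)) stop("duplicate edges are not allowed")
  }
  structure(list(n_nodes = n_nodes, edges = edges), class = "cell_graph")
}

# sort each pair (i < j) and order rows lexicographically
canonical_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  dimnames(e) <- NULL
  e
}

#' @method print cell_graph
#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Number of edges in a cell graph
#' @param graph a `cell_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Dense adjacency matrix of a cell graph
#' @param graph a `cell_graph`.
#' @param self_loops add the identity (used for attention neighbourhoods).
#' @return `n_nodes` x `n_nodes` 0/1 matrix.
#' @export
adjacency_matrix <- function(graph, self_loops = FALSE) {
  a <- matrix(0, graph$n_nodes, graph$n_nodes)
  if (nrow(graph$edges)) {
    a[graph$edges] <- 1
    a[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  if (self_loops) diag(a) <- 1
  a
}

#' Build a k-nearest-neighbour cell graph
#'
#' Connects each cell to its `k` nearest neighbours under the chosen metric
#' and symmetrizes the directed neighbour lists by union (an edge is kept if
#' either endpoint selects the other), yielding a simple undirected graph.
#' For `pearson` and `cosine`, "nearest" means highest correlation /
#' similarity; ranking uses the equivalent distances `1 - r`. Neighbour ties
#' are broken in favour of the lower cell index, so construction is
#' deterministic.
#'
#' Optionally the features are first restricted to the `khvg` most variable
#' genes (the gene subset used for graph construction may differ from the
#' node features) and/or projected to `use_pca` principal components.
#'
#' @param features an `sc_expr` (typically log-normalized and scaled).
#' @param k neighbours per cell; must satisfy `k < n_cells`.
#' @param metric one of `"euclidean"`, `"pearson"`, `"cosine"`,
#'   `"manhattan"`.
#' @param khvg optional number of top highly variable genes to compute
#'   distances on.
#' @param use_pca optional number of principal components to project to
#'   before computing distances.
#' @return A `cell_graph`.
#' @export
build_knn_graph <- function(features, k,
                            metric = c("euclidean", "pearson", "cosine", "manhattan"),
                            khvg = NULL, use_pca = NULL) {
  stopifnot(inherits(features, "sc_expr"))
  metric <- match.arg(metric)
  n <- nrow(features$values)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be a single positive integer")
  }
  if (k >= n) stop(sprintf("k (%d) must be smaller than the number of cells (%d)", k, n))
  v <- features$values
  if (!is.null(khvg)) {
    if (khvg > ncol(v)) stop("khvg exceeds the number of genes")
    v <- v[, select_hvg(features, khvg), drop = FALSE]
  }
  if (!is.null(use_pca)) {
    npc <- min(use_pca, n - 1L, ncol(v))
    v <- stats::prcomp(v, center = TRUE, scale. = FALSE)$x[, seq_len(npc), drop = FALSE]
  }
  d <- pairwise_distances(v, metric, features$cell_ids)
  edges_from_knn(d, k)
}

# full pairwise distance matrix; pearson/cosine mapped to 1 - similarity so
# that smaller always means nearer
pairwise_distances <- function(v, metric, cell_ids = NULL) {
  if (metric %in% c("euclidean", "manhattan")) {
    as.matrix(stats::dist(v, method = metric))
  } else if (metric == "pearson") {
    sds <- apply(v, 1, stats::sd)
    if (any(sds == 0)) {
      bad <- which(sds == 0)[1]
      id <- if (is.null(cell_ids)) as.character(bad) else cell_ids[bad]
      stop(sprintf("cell '%s' has zero variance; Pearson correlation is undefined", id))
    }
    1 - stats::cor(t(v))
  } else { # cosine
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm == 0)) {
      bad <- which(nrm == 0)[1]
      id <- if (is.null(cell_ids)) as.character(bad) else cell_ids[bad]
      stop(sprintf("cell '%s' is all-zero; cosine similarity is undefined", id))
    }
    1 - (v %*% t(v)) / outer(nrm, nrm)
  }
}

# per row: the k smallest off-diagonal distances, ties to lower index;
# directed lists symmetrized by union
edges_from_knn <- function(d, k) {
  n <- nrow(d)
  src <- integer(n * k)
  dst <- integer(n * k)
  for (i in seq_len(n)) {
    row <- d[i, ]
    row[i] <- Inf
    nb <- order(row, seq_len(n))[seq_len(k)]
    idx <- ((i - 1) * k + 1):(i * k)
    src[idx] <- i
    dst[idx] <- nb
  }
  e <- unique(canonical_edges(cbind(src, dst)))
  cell_graph(n, e)
}

#' Read a custom cell graph from an edge-list file
#'
#' Parses a whitespace-separated two-column file of 0-based node indices
#' into a validated `cell_graph`. Self-loops are dropped with a warning,
#' duplicate edges (including reversed duplicates) are collapsed, and
#' out-of-range indices raise an error naming the offending line.
#'
#' @param path path to the edge-list file.
#' @param n_nodes number of nodes the graph is defined over.
#' @return A `cell_graph`.
#' @export
read_edge_list <- function(path, n_nodes) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  src <- integer(0); dst <- integer(0)
  for (ln in keep) {
    parts <- strsplit(trimws(lines[ln]), "[[:space:],]+")[[1]]
    if (length(parts) < 2) {
      stop(sprintf("line %d of '%s': expected two integer columns", ln, path))
    }
    ij <- suppressWarnings(as.integer(parts[1:2]))
    if (anyNA(ij)) {
      stop(sprintf("line %d of '%s': not parseable as integers", ln, path))
    }
    if (any(ij < 0) || any(ij >= n_nodes)) {
      stop(sprintf("line %d of '%s': index out of range [0, %d)", ln, path, n_nodes))
    }
    src <- c(src, ij[1]); dst <- c(dst, ij[2])
  }
  e <- cbind(src, dst) + 1L  # file is 0-based, internal indices are 1-based
  loops <- e[, 1] == e[, 2]
  if (any(loops)) {
    warning(sprintf("%d self-loop(s) dropped from '%s'", sum(loops), path))
    e <- e[!loops, , drop = FALSE]
  }
  e <- unique(canonical_edges(e))
  cell_graph(n_nodes, e)
}

#' Write a cell graph as a 0-based edge-list TSV
#'
#' @param graph a `cell_graph`.
#' @param path output file path.
#' @param header optional comment line (written prefixed with `#`).
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(graph$edges)) {
    utils::write.table(graph$edges - 1L, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Apply a node relabelling to a cell graph
#'
#' @param graph a `cell_graph`.
#' @param perm integer permutation of `1:n_nodes`; node `i` becomes
#'   `perm[i]`.
#' @return The relabelled `cell_graph`.
#' @export
permute_graph <- function(graph, perm) {
  stopifnot(length(perm) == graph$n_nodes, !anyDuplicated(perm))
  e <- graph$edges
  cell_graph(graph$n_nodes, cbind(perm[e[, 1]], perm[e[, 2]]))
}

# neighbour list (no self), used by the layer forward passes
neighbour_list <- function(graph) {
  nb <- vector("list", graph$n_nodes)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges[r, 1]; j <- graph$edges[r, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}
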