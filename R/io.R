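#' Read an expression matrix from disk
#'
#' Two dialects are supported. `"mtx"`: a 10x-style directory (or a
#' `matrix.mtx` file with sidecars in the same directory) holding a Matrix
#' Market sparse matrix with genes in rows and cells in columns, a
#' `barcodes.tsv` with one cell id per line and a `features.tsv` (or
#' `genes.tsv`) whose first column is the gene id. `"csv"`: a dense table
#' with cells in rows, a header row of gene ids and the cell id in the
#' first column. Lines starting with `#` are ignored.
#'
#' @param path directory or file path.
#' @param format `"auto"` (directories and `.mtx` files are Matrix Market,
#'   everything else CSV), `"mtx"`, or `"csv"`.
#' @return An `sc_expr` (cells in rows).
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (format == "mtx") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx_path <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    if (!file.exists(mtx_path)) stop(sprintf("matrix file not found: %s", mtx_path))
    bar_path <- file.path(dir, "barcodes.tsv")
    feat_path <- file.path(dir, "features.tsv")
    if (!file.exists(feat_path)) feat_path <- file.path(dir, "genes.tsv")
    if (!file.exists(bar_path)) stop(sprintf("barcodes.tsv not found in %s", dir))
    if (!file.exists(feat_path)) stop(sprintf("features.tsv/genes.tsv not found in %s", dir))
    m <- Matrix::readMM(mtx_path)          # genes x cells (10x convention)
    barcodes <- readLines(bar_path)
    feats <- utils::read.table(feat_path, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
    if (length(barcodes) != ncol(m)) {
      stop(sprintf("barcode count (%d) does not match matrix columns (%d) in %s",
                   length(barcodes), ncol(m), dir))
    }
    if (nrow(feats) != nrow(m)) {
      stop(sprintf("feature count (%d) does not match matrix rows (%d) in %s",
                   nrow(feats), nrow(m), dir))
    }
    expression_matrix(t(as.matrix(m)), cell_ids = barcodes,
                      gene_ids = feats[[1]])
  } else {
    tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop(sprintf("malformed CSV (need id column + genes): %s", path))
    cell_ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals)) stop(sprintf("non-numeric expression values in %s", path))
    expression_matrix(vals, cell_ids = cell_ids,
                      gene_ids = colnames(tab)[-1])
  }
}

#' Write an expression matrix to disk
#'
#' @param expr an `sc_expr`.
#' @param path output directory (mtx) or file (csv).
#' @param format `"mtx"` or `"csv"` (see [read_expression()]).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(expr, "sc_expr"))
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- Matrix::Matrix(t(expr$values), sparse = TRUE)
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(expr$cell_ids, file.path(path, "barcodes.tsv"))
    utils::write.table(data.frame(expr$gene_ids, expr$gene_ids),
                       file.path(path, "features.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    tab <- data.frame(cell_id = expr$cell_ids, expr$values,
                      check.names = FALSE)
    colnames(tab) <- c("cell_id", expr$gene_ids)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# 32-bit FNV-1a hash of a string, as 8 hex digits; used to stamp every
# pipeline output with the configuration that produced it
fnv1a_hash <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    h <- xor32(h, b)
    # 32-bit modular multiply by the FNV prime, split into 16-bit halves so
    # intermediate products stay within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  # h can exceed .Machine$integer.max; format the halves separately
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# bitwXor works on 32-bit signed ints; operate on halves to stay unsigned
xor32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}

#' Create a pipeline run configuration
#'
#' All settings of the end-to-end workflow in one serializable object:
#' input location, preprocessing, graph construction, model/training
#' settings (see [training_config()]), clustering and output directory.
#'
#' @param input path to the expression input (CSV file or MTX directory).
#' @param outdir output directory for artifacts.
#' @param graph `"knn"` (Euclidean), `"pknn"` (Pearson) or `"custom"`.
#' @param custom_graph path to a 0-based edge-list file (for
#'   `graph = "custom"`).
#' @param input_format `"auto"`, `"mtx"` or `"csv"`.
#' @param target_sum library-size normalization target.
#' @param n_hvg,khvg highly variable genes used as node features / for
#'   graph construction.
#' @param k,use_pca neighbour count and optional PCA width for the graph.
#' @param hidden_dims,n_heads,latent_dim,reg_kind,use_feature_recon,epochs,learning_rate,holdout_fraction
#'   training settings, as in [training_config()].
#' @param min_cluster_size HDBSCAN minimum cluster size (`NULL` = default
#'   heuristic).
#' @param rescue_min_size if non-`NULL`, rescue small clusters from noise
#'   with this reduced minimum size.
#' @param reference_labels optional path to a CSV with columns
#'   `cell_id,label` for ARI evaluation.
#' @param seed master seed for the whole run.
#' @param verbose print per-stage progress.
#' @return A `run_config` list.
#' @export
run_config <- function(input, outdir, graph = c("pknn", "knn", "custom"),
                       custom_graph = NULL, input_format = "auto",
                       target_sum = 1e4, n_hvg = 250, khvg = 250,
                       k = 5, use_pca = NULL,
                       hidden_dims = c(32, 32), n_heads = 2,
                       latent_dim = 16, reg_kind = "kl",
                       use_feature_recon = FALSE, epochs = 200,
                       learning_rate = 1e-3, holdout_fraction = 0,
                       min_cluster_size = NULL, rescue_min_size = NULL,
                       reference_labels = NULL, seed = 1L, verbose = TRUE) {
  graph <- match.arg(graph)
  cfg <- list(input = input, outdir = outdir, graph = graph,
              custom_graph = custom_graph, input_format = input_format,
              target_sum = target_sum, n_hvg = n_hvg, khvg = khvg, k = k,
              use_pca = use_pca, hidden_dims = hidden_dims,
              n_heads = n_heads, latent_dim = latent_dim,
              reg_kind = reg_kind, use_feature_recon = use_feature_recon,
              epochs = epochs, learning_rate = learning_rate,
              holdout_fraction = holdout_fraction,
              min_cluster_size = min_cluster_size,
              rescue_min_size = rescue_min_size,
              reference_labels = reference_labels,
              seed = as.integer(seed), verbose = verbose)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected so typos cannot silently change a run.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Write a run configuration to a YAML file
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

config_hash <- function(config) {
  fnv1a_hash(paste(utils::capture.output(utils::str(unclass(config))),
                   collapse = "\n"))
}
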