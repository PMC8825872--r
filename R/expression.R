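#' Construct an expression matrix container
#'
#' Bundles a dense cells-by-genes matrix of non-negative expression values
#' with cell and gene identifiers, plus a record of the normalization steps
#' already applied. This is the node-feature source for the graph
#' autoencoder: after preprocessing, row i of `values` is the feature vector
#' of cell i.
#'
#' @param values numeric matrix, cells in rows, genes in columns. Must be
#'   finite; raw counts must be non-negative.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#'   Defaults to `cell_1 .. cell_N`.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column. Defaults to `gene_1 .. gene_D`.
#' @param normalized character vector naming transforms already applied
#'   (e.g. `"log_normalize"`, `"minmax_scale"`); empty for raw counts.
#'
#' @return An object of class `sc_expr`: a list with elements `values`,
#'   `cell_ids`, `gene_ids`, `normalized`.
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                              normalized = character()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite (no NA/NaN/Inf)")
  }
  if (length(normalized) == 0 && any(values < 0)) {
    stop("raw expression counts must be non-negative")
  }
  n <- nrow(values)
  d <- ncol(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(d))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n) {
    stop(sprintf("cell_ids length (%d) does not match number of rows (%d)",
                 length(cell_ids), n))
  }
  if (length(gene_ids) != d) {
    stop(sprintf("gene_ids length (%d) does not match number of columns (%d)",
                 length(gene_ids), d))
  }
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  dimnames(values) <- NULL
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         normalized = as.character(normalized)),
    class = "sc_expr"
  )
}

#' @method print sc_expr
#' @export
print.sc_expr <- function(x, ...) {
  cat(sprintf("<sc_expr> %d cells x %d genes", nrow(x$values), ncol(x$values)))
  if (length(x$normalized)) {
    cat(" | transforms:", paste(x$normalized, collapse = " -> "))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.sc_expr <- function(x) dim(x$values)

#' Subset an expression matrix by cells and/or genes
#'
#' @param x an `sc_expr` object.
#' @param cells,genes integer or logical indices (standard R subsetting).
#' @return An `sc_expr` with the selected rows/columns; the transform record
#'   is retained.
#' @export
subset_expression <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "sc_expr"))
  v <- x$values
  ci <- x$cell_ids
  gi <- x$gene_ids
  if (!is.null(cells)) {
    v <- v[cells, , drop = FALSE]
    ci <- ci[cells]
  }
  if (!is.null(genes)) {
    v <- v[, genes, drop = FALSE]
    gi <- gi[genes]
  }
  expression_matrix(v, ci, gi, normalized = x$normalized)
}
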