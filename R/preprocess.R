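#' Library-size normalize and log-transform counts
#'
#' Scales every cell's counts to a common total (`target_sum`), then applies
#' the natural-log `log1p` transform. This is the standard "log-normalize"
#' step of single-cell workflows: it removes library-size differences
#' between cells and compresses the dynamic range of counts.
#'
#' @param counts an `sc_expr` of non-negative counts.
#' @param target_sum positive total each cell is scaled to (default 10000,
#'   the common counts-per-ten-thousand convention).
#' @return An `sc_expr` with values `log1p(counts * target_sum / cell_total)`
#'   and `"log_normalize"` appended to the transform record.
#' @export
log_normalize <- function(counts, target_sum = 1e4) {
  stopifnot(inherits(counts, "sc_expr"))
  if (!is.numeric(target_sum) || length(target_sum) != 1 || target_sum <= 0) {
    stop("target_sum must be a single positive number")
  }
  if (any(counts$values < 0)) stop("counts must be non-negative")
  totals <- rowSums(counts$values)
  if (any(totals == 0)) {
    bad <- counts$cell_ids[which(totals == 0)[1]]
    stop(sprintf("cell '%s' has zero total counts and cannot be normalized", bad))
  }
  scaled <- counts$values * (target_sum / totals)
  expression_matrix(log1p(scaled), counts$cell_ids, counts$gene_ids,
                    normalized = c(counts$normalized, "log_normalize"))
}

#' Min-max scale each gene to the unit interval
#'
#' Per-gene affine rescaling `(x - min) / (max - min)` so every gene column
#' lies in `[0, 1]`, putting genes on a common scale before they are used as
#' node features. Constant genes (max == min) carry no signal and are mapped
#' to all-zeros rather than an arbitrary constant.
#'
#' @param matrix an `sc_expr` with finite values.
#' @return An `sc_expr` with each column in `[0, 1]` and `"minmax_scale"`
#'   appended to the transform record.
#' @export
minmax_scale <- function(matrix) {
  stopifnot(inherits(matrix, "sc_expr"))
  v <- matrix$values
  mins <- apply(v, 2, min)
  maxs <- apply(v, 2, max)
  rng <- maxs - mins
  out <- sweep(v, 2, mins, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  expression_matrix(out, matrix$cell_ids, matrix$gene_ids,
                    normalized = c(matrix$normalized, "minmax_scale"))
}

#' Select highly variable genes by dispersion
#'
#' Ranks genes by dispersion (variance / mean) of the supplied values —
#' intended to be log-normalized expression — and returns the indices of the
#' `n_top` most dispersed genes. Genes with zero mean (all-zero columns) get
#' dispersion 0. Ties are broken in favour of the lower gene index so the
#' selection is fully deterministic and invariant to cell order.
#'
#' @param matrix an `sc_expr`, normally log-normalized.
#' @param n_top number of genes to select; must not exceed the gene count.
#' @return Integer vector of `n_top` gene column indices, ordered from most
#'   to least dispersed.
#' @export
select_hvg <- function(matrix, n_top) {
  stopifnot(inherits(matrix, "sc_expr"))
  d <- ncol(matrix$values)
  if (!is.numeric(n_top) || length(n_top) != 1 || n_top < 1 || n_top != round(n_top)) {
    stop("n_top must be a single positive integer")
  }
  if (n_top > d) {
    stop(sprintf("n_top (%d) exceeds the number of genes (%d)", n_top, d))
  }
  disp <- gene_dispersion(matrix$values)
  # order by decreasing dispersion, ties to the lower gene index
  ord <- order(-disp, seq_len(d))
  ord[seq_len(n_top)]
}

# variance/mean per gene column; 0 where the mean is 0 (all-zero column,
# since values are non-negative after log-normalization)
gene_dispersion <- function(v) {
  mu <- colMeans(v)
  n <- nrow(v)
  if (n > 1) {
    va <- colSums(sweep(v, 2, mu, "-")^2) / (n - 1)
  } else {
    va <- rep(0, ncol(v))
  }
  disp <- rep(0, ncol(v))
  ok <- mu != 0
  disp[ok] <- va[ok] / mu[ok]
  disp
}
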