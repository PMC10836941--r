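#' Paired single-cell multiome container
#'
#' Bundles the two modality matrices of a paired RNA + ATAC single-cell
#' experiment together with the cell-cell neighborhood graph and cell
#' metadata. All matrices share one cell ordering; the metadata table is the
#' authority for that ordering.
#'
#' @param rna cell x gene matrix of nonnegative normalized expression values
#'   (dense or \code{Matrix} sparse). Typically library-size-normalized and
#'   log1p-transformed counts.
#' @param atac cell x peak matrix of nonnegative accessibility values.
#' @param cell_meta data.frame keyed by a \code{cell_id} column; typically
#'   also carries a group label column (cluster annotation), a
#'   \code{pseudotime} column (nonnegative, may contain \code{NA}) and a
#'   trajectory \code{path} label.
#' @param connectivities n x n sparse nonnegative cell-cell connectivity
#'   matrix, e.g. the weighted nearest-neighbor (WNN) graph connectivities.
#'   The diagonal is kept as provided (usually zero).
#' @param embedding optional n x 2 matrix of 2-D embedding coordinates.
#' @param gene_ids,peak_ids optional character vectors overriding the matrix
#'   column names. Peak ids are expected to be coordinate-encoded
#'   (\code{"chr1:1000-2000"} or \code{"chr1-1000-2000"}).
#'
#' @return An object of class \code{paired_omics}: a list with elements
#'   \code{rna}, \code{atac}, \code{cell_ids}, \code{gene_ids},
#'   \code{peak_ids}, \code{connectivities}, \code{cell_meta},
#'   \code{embedding}.
#' @export
paired_omics <- function(rna, atac, cell_meta, connectivities,
                         embedding = NULL, gene_ids = NULL, peak_ids = NULL) {
  rna <- methods::as(as_sparse(rna), "CsparseMatrix")
  atac <- methods::as(as_sparse(atac), "CsparseMatrix")
  if (!is.data.frame(cell_meta) || !("cell_id" %in% names(cell_meta))) {
    stop_validation("'cell_meta' must be a data.frame with a 'cell_id' column")
  }
  cell_ids <- as.character(cell_meta$cell_id)
  gene_ids <- as.character(gene_ids %||% colnames(rna))
  peak_ids <- as.character(peak_ids %||% colnames(atac))
  if (is.null(gene_ids) || length(gene_ids) != ncol(rna)) {
    stop_validation("gene ids missing or of wrong length for the RNA matrix")
  }
  if (is.null(peak_ids) || length(peak_ids) != ncol(atac)) {
    stop_validation("peak ids missing or of wrong length for the ATAC matrix")
  }
  obj <- structure(
    list(rna = rna, atac = atac, cell_ids = cell_ids,
         gene_ids = gene_ids, peak_ids = peak_ids,
         connectivities = methods::as(as_sparse(connectivities), "CsparseMatrix"),
         cell_meta = cell_meta,
         embedding = if (!is.null(embedding)) as.matrix(embedding) else NULL),
    class = "paired_omics")
  validate_paired_omics(obj)
}

as_sparse <- function(m) {
  if (inherits(m, "sparseMatrix")) return(m)
  Matrix::Matrix(as.matrix(m), sparse = TRUE)
}

#' Validate a paired_omics object
#'
#' Checks the structural invariants: consistent cell ordering and counts
#' (n >= 2), unique feature and cell ids, nonnegative connectivities.
#'
#' @param x a \code{paired_omics} object.
#' @return \code{x}, invisibly unchanged, or an error.
#' @export
validate_paired_omics <- function(x) {
  n <- length(x$cell_ids)
  if (n < 2L) stop_validation("need at least 2 cells, got %d", n)
  if (anyDuplicated(x$cell_ids)) stop_validation("duplicate cell ids")
  if (anyDuplicated(x$gene_ids)) stop_validation("duplicate gene ids")
  if (anyDuplicated(x$peak_ids)) stop_validation("duplicate peak ids")
  if (nrow(x$rna) != n) {
    stop_validation("RNA matrix has %d rows but there are %d cells",
                    nrow(x$rna), n)
  }
  if (nrow(x$atac) != n) {
    stop_validation("ATAC matrix has %d rows but there are %d cells",
                    nrow(x$atac), n)
  }
  if (ncol(x$rna) != length(x$gene_ids)) {
    stop_validation("RNA matrix has %d columns but %d gene ids",
                    ncol(x$rna), length(x$gene_ids))
  }
  if (ncol(x$atac) != length(x$peak_ids)) {
    stop_validation("ATAC matrix has %d columns but %d peak ids",
                    ncol(x$atac), length(x$peak_ids))
  }
  if (!all(dim(x$connectivities) == c(n, n))) {
    stop_validation("connectivities must be %d x %d", n, n)
  }
  if (length(x$connectivities@x) && min(x$connectivities@x) < 0) {
    stop_validation("connectivities contains negative entries")
  }
  if (min(x$rna) < 0 || min(x$atac) < 0) {
    stop_validation("modality matrices must be nonnegative")
  }
  if (!is.null(x$embedding) &&
      (nrow(x$embedding) != n || ncol(x$embedding) != 2L)) {
    stop_validation("embedding must be an n x 2 matrix")
  }
  invisible(x)
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf("paired_omics: %d cells, %d genes, %d peaks\n",
              length(x$cell_ids), length(x$gene_ids), length(x$peak_ids)))
  cat(sprintf("  graph: %d nonzero connectivities\n",
              length(x$connectivities@x)))
  cat(sprintf("  cell_meta columns: %s\n",
              paste(names(x$cell_meta), collapse = ", ")))
  if (!is.null(x$embedding)) cat("  embedding: present\n")
  invisible(x)
}

#' @export
summary.paired_omics <- function(object, ...) {
  cat(sprintf("paired_omics with %d cells\n", length(object$cell_ids)))
  cat(sprintf("  RNA:  %d genes, %.1f%% zero entries\n", length(object$gene_ids),
              100 * (1 - length(object$rna@x) / prod(dim(object$rna)))))
  cat(sprintf("  ATAC: %d peaks, %.1f%% zero entries\n", length(object$peak_ids),
              100 * (1 - length(object$atac@x) / prod(dim(object$atac)))))
  invisible(object)
}

#' Reorder the cells of a paired_omics object
#'
#' Applies one permutation consistently to both modality matrices, the graph
#' (rows and columns), the metadata and the embedding.
#'
#' @param data a \code{paired_omics} object.
#' @param order_idx integer permutation of \code{seq_along(data$cell_ids)}.
#' @return the reordered \code{paired_omics}.
#' @export
reorder_cells <- function(data, order_idx) {
  n <- length(data$cell_ids)
  if (!identical(sort(as.integer(order_idx)), seq_len(n))) {
    stop_validation("'order_idx' must be a permutation of 1..%d", n)
  }
  meta <- data$cell_meta[order_idx, , drop = FALSE]
  rownames(meta) <- NULL
  paired_omics(rna = data$rna[order_idx, , drop = FALSE],
               atac = data$atac[order_idx, , drop = FALSE],
               cell_meta = meta,
               connectivities = data$connectivities[order_idx, order_idx],
               embedding = if (!is.null(data$embedding))
                 data$embedding[order_idx, , drop = FALSE] else NULL,
               gene_ids = data$gene_ids, peak_ids = data$peak_ids)
}
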