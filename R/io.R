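# Reading and writing the MTX/TSV interchange bundle.
#
# A bundle directory contains:
#   rna.mtx, atac.mtx, graph.mtx   sparse matrices in Matrix Market format
#   cells.tsv                      cell ids in matrix row order (header: cell_id)
#   genes.tsv, peaks.tsv           feature ids in column order
#   meta.tsv                       cell metadata; its row order is authoritative
#   embedding.tsv                  optional n x 2 coordinates
# Cell order in the matrices is reconciled against meta.tsv on read: matrices
# are reordered to the metadata order, never the reverse.

#' Write a paired_omics bundle to a directory
#'
#' Emits sparse Matrix Market matrices with TSV sidecars. Writers are
#' deterministic: fixed field order, tab delimiter, LF line endings.
#'
#' @param data a \code{paired_omics} object.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_paired_omics <- function(data, dir) {
  validate_paired_omics(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(data$rna, file.path(dir, "rna.mtx"))
  Matrix::writeMM(data$atac, file.path(dir, "atac.mtx"))
  Matrix::writeMM(data$connectivities, file.path(dir, "graph.mtx"))
  write_tsv(data.frame(cell_id = data$cell_ids), file.path(dir, "cells.tsv"))
  write_tsv(data.frame(gene_id = data$gene_ids), file.path(dir, "genes.tsv"))
  write_tsv(data.frame(peak_id = data$peak_ids), file.path(dir, "peaks.tsv"))
  write_tsv(data$cell_meta, file.path(dir, "meta.tsv"))
  if (!is.null(data$embedding)) {
    emb <- data.frame(dim1 = data$embedding[, 1], dim2 = data$embedding[, 2])
    write_tsv(emb, file.path(dir, "embedding.tsv"))
  }
  invisible(dir)
}

read_mm <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  m <- Matrix::readMM(path)
  methods::as(m, "CsparseMatrix")
}

#' Read a paired_omics bundle
#'
#' Loads the MTX/TSV bundle written by \code{\link{write_paired_omics}}. The
#' row order of \code{meta.tsv} is the cell-order authority: all matrices are
#' reordered to match it.
#'
#' @param dir bundle directory, or \code{NULL} if explicit paths are given.
#' @param rna_path,atac_path,meta_path,graph_path optional explicit file
#'   paths overriding the bundle layout.
#' @return a validated \code{paired_omics} object.
#' @export
read_paired_omics <- function(dir = NULL, rna_path = NULL, atac_path = NULL,
                              meta_path = NULL, graph_path = NULL) {
  p <- function(default, override) override %||%
    (if (!is.null(dir)) file.path(dir, default) else
       stop_io("either 'dir' or all explicit paths must be given"))
  rna_path <- p("rna.mtx", rna_path)
  atac_path <- p("atac.mtx", atac_path)
  meta_path <- p("meta.tsv", meta_path)
  graph_path <- p("graph.mtx", graph_path)
  cells_path <- if (!is.null(dir)) file.path(dir, "cells.tsv") else
    file.path(dirname(meta_path), "cells.tsv")
  genes_path <- file.path(dirname(rna_path), "genes.tsv")
  peaks_path <- file.path(dirname(atac_path), "peaks.tsv")

  rna <- read_mm(rna_path)
  atac <- read_mm(atac_path)
  graph <- read_mm(graph_path)
  meta <- read_tsv(meta_path)
  cells <- read_tsv(cells_path)$cell_id
  genes <- read_tsv(genes_path)$gene_id
  peaks <- read_tsv(peaks_path)$peak_id

  if (!("cell_id" %in% names(meta))) {
    stop_validation("%s lacks a 'cell_id' column", meta_path)
  }
  if (anyDuplicated(meta$cell_id)) {
    stop_validation("duplicate cell ids in %s", meta_path)
  }
  if (anyDuplicated(cells)) stop_validation("duplicate cell ids in %s", cells_path)
  if (nrow(rna) != length(cells)) {
    stop_io("dimension mismatch: %s has %d rows but %s lists %d cells",
            rna_path, nrow(rna), cells_path, length(cells))
  }
  if (nrow(atac) != length(cells)) {
    stop_io("dimension mismatch: %s has %d rows but %s lists %d cells",
            atac_path, nrow(atac), cells_path, length(cells))
  }
  if (ncol(rna) != length(genes)) {
    stop_io("dimension mismatch: %s has %d columns but %s lists %d genes",
            rna_path, ncol(rna), genes_path, length(genes))
  }
  if (ncol(atac) != length(peaks)) {
    stop_io("dimension mismatch: %s has %d columns but %s lists %d peaks",
            atac_path, ncol(atac), peaks_path, length(peaks))
  }
  if (!all(dim(graph) == length(cells))) {
    stop_io("dimension mismatch: %s is %d x %d but there are %d cells",
            graph_path, nrow(graph), ncol(graph), length(cells))
  }
  if (nrow(meta) != length(cells) || !setequal(meta$cell_id, cells)) {
    stop_io("dimension mismatch: %s lists %d cells that do not match %s",
            meta_path, nrow(meta), cells_path)
  }
  # metadata row order is authoritative; reorder matrices to it
  idx <- match(meta$cell_id, cells)

  emb <- NULL
  emb_path <- if (!is.null(dir)) file.path(dir, "embedding.tsv") else
    file.path(dirname(meta_path), "embedding.tsv")
  if (file.exists(emb_path)) {
    e <- read_tsv(emb_path)
    emb <- as.matrix(e[idx, c("dim1", "dim2")])
    rownames(emb) <- NULL
  }
  paired_omics(rna = rna[idx, , drop = FALSE],
               atac = atac[idx, , drop = FALSE],
               cell_meta = meta,
               connectivities = graph[idx, idx],
               embedding = emb, gene_ids = genes, peak_ids = peaks)
}

#' Write a gene-peak pair table as TSV
#' @param pairs a \code{pair_table}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  write_tsv(as.data.frame(pairs), path)
}

#' Read a gene-peak pair table from TSV
#' @param path TSV written by \code{\link{write_pair_table}}.
#' @return a \code{pair_table} data.frame.
#' @export
read_pair_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "peak_id", "distance_bp", "relation")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_validation("pair table %s lacks columns: %s", path,
                    paste(miss, collapse = ", "))
  }
  as_pair_table(df)
}

#' Write a local correlation result
#'
#' Emits \code{local_L.tsv} (dense cell x pair matrix with a header of pair
#' keys), \code{pairs.tsv} (the pair table defining column order) and
#' \code{global_L.tsv} (two columns: pair key and global index).
#'
#' @param lc a \code{local_corr} object.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_local_corr <- function(lc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  L <- as.data.frame(lc$L, check.names = FALSE)
  L <- cbind(data.frame(cell_id = rownames(lc$L)), L)
  write_tsv(L, file.path(dir, "local_L.tsv"))
  write_pair_table(lc$pairs, file.path(dir, "pairs.tsv"))
  write_tsv(data.frame(pair_key = names(lc$global_index),
                       global_L = unname(lc$global_index)),
            file.path(dir, "global_L.tsv"))
  invisible(dir)
}

#' Read a local correlation result written by \code{\link{write_local_corr}}
#' @param dir directory holding \code{local_L.tsv}, \code{pairs.tsv},
#'   \code{global_L.tsv}.
#' @return a \code{local_corr} object.
#' @export
read_local_corr <- function(dir) {
  ltab <- read_tsv(file.path(dir, "local_L.tsv"))
  pairs <- read_pair_table(file.path(dir, "pairs.tsv"))
  gl <- read_tsv(file.path(dir, "global_L.tsv"))
  L <- as.matrix(ltab[, -1, drop = FALSE])
  rownames(L) <- ltab$cell_id
  structure(list(L = L, pairs = pairs,
                 global_index = stats::setNames(gl$global_L, gl$pair_key),
                 zeroed_dropouts = NA, n_dropped = NA_integer_),
            class = "local_corr")
}
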