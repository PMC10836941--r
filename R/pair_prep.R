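# Data-preparation module: per-group feature sparsity QC and gene-peak
# pairing by genomic window or TF binding sites.

as_pair_table <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("pair_table", "data.frame")
  df
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("pair_table: %d gene-peak pairs (%d genes, %d peaks)\n",
              nrow(x), length(unique(x$gene_id)), length(unique(x$peak_id))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  invisible(x)
}

pair_key <- function(pairs) paste(pairs$gene_id, pairs$peak_id, sep = "|")

# deterministic row order: gene_id, then distance ascending, then peak_id
order_pair_table <- function(df) {
  df <- df[order(df$gene_id, df$distance_bp, df$peak_id), , drop = FALSE]
  df[!duplicated(paste(df$gene_id, df$peak_id)), , drop = FALSE]
}

#' Per-group feature sparsity
#'
#' Computes, for every gene and peak, the fraction of exactly-zero entries
#' within each cell group. Sparsity is the key quality metric for selecting
#' gene-peak pairs: features that are almost entirely zero in a group carry
#' little correlation information there and are dominated by dropout.
#'
#' @param data a \code{paired_omics} object.
#' @param group_key name of the grouping column in \code{data$cell_meta}.
#' @return a \code{sparsity_report} data.frame with columns
#'   \code{feature_id}, \code{modality} ("rna"/"atac"), \code{group},
#'   \code{n_cells}, \code{zero_fraction}.
#' @export
feature_sparsity <- function(data, group_key) {
  validate_paired_omics(data)
  if (!(group_key %in% names(data$cell_meta))) {
    stop_validation("group key '%s' not found in cell_meta", group_key)
  }
  groups <- as.factor(data$cell_meta[[group_key]])
  if (any(table(groups) == 0L)) stop_validation("empty group level present")
  one_modality <- function(m, ids, modality) {
    res <- lapply(levels(groups), function(g) {
      idx <- which(groups == g)
      nz <- Matrix::colSums(m[idx, , drop = FALSE] != 0)
      data.frame(feature_id = ids, modality = modality, group = g,
                 n_cells = length(idx),
                 zero_fraction = (length(idx) - as.numeric(nz)) / length(idx),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  out <- rbind(one_modality(data$rna, data$gene_ids, "rna"),
               one_modality(data$atac, data$peak_ids, "atac"))
  rownames(out) <- NULL
  class(out) <- c("sparsity_report", "data.frame")
  out
}

#' Pair genes with nearby peaks by genomic window
#'
#' A pair (gene, peak) is formed whenever the peak interval intersects the
#' gene body extended by \code{window_bp} on both sides (half-open interval
#' arithmetic, same chromosome). \code{distance_bp} is the gap between the
#' peak and the unextended gene body (0 when they overlap); \code{relation}
#' labels the peak as \code{overlap}, \code{upstream} (5' of the gene on its
#' strand) or \code{downstream}. The row order (gene id, then distance, then
#' peak id) is deterministic and defines the column indexing of the local
#' correlation matrix downstream.
#'
#' @param data a \code{paired_omics} object.
#' @param gene_annot interval table from \code{\link{read_gene_annotation}}
#'   (columns \code{gene_id}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}; 0-based half-open).
#' @param window_bp nonnegative window size in bp; default 100000 (100 kb),
#'   a common cis-regulatory search range.
#' @param tss_anchored if \code{TRUE}, the window is anchored at the
#'   transcription start site instead of the gene body (the gene interval is
#'   collapsed to its strand-aware 5' end before extension).
#' @return a \code{pair_table} data.frame.
#' @export
pair_by_window <- function(data, gene_annot, window_bp = 100000L,
                           tss_anchored = FALSE) {
  validate_paired_omics(data)
  if (!is.data.frame(gene_annot) || nrow(gene_annot) == 0L) {
    stop_validation("empty gene annotation")
  }
  if (window_bp < 0) stop_validation("'window_bp' must be >= 0")
  window_bp <- as.integer(window_bp)

  ann <- gene_annot[gene_annot$gene_id %in% data$gene_ids, , drop = FALSE]
  n_skip <- length(setdiff(data$gene_ids, ann$gene_id))
  if (n_skip > 0L) {
    log_msg(sprintf("pair_by_window: %d gene(s) without annotation skipped",
                    n_skip))
  }
  if (tss_anchored) {
    tss <- ifelse(ann$strand == "-", ann$end - 1L, ann$start)
    ann$start <- tss
    ann$end <- tss + 1L
  }
  peaks <- parse_peak_id(data$peak_ids)
  peaks$peak_id <- data$peak_ids

  if (nrow(ann) == 0L) {
    warning("no annotated genes present in the data; empty pair table")
    return(empty_pair_table())
  }

  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(ann, pad = window_bp),
    intervals_to_granges(peaks))
  gi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  if (!length(gi)) {
    warning("no gene-peak pairs found within the window")
    return(empty_pair_table())
  }
  gs <- ann$start[gi]; ge <- ann$end[gi]
  ps <- peaks$start[pi]; pe <- peaks$end[pi]
  strand <- ann$strand[gi]
  # gap between half-open intervals; 0 on overlap
  dist <- pmax(0L, pmax(gs - pe, ps - ge))
  right_of_gene <- ps >= ge
  left_of_gene <- pe <= gs
  relation <- rep("overlap", length(gi))
  plus_like <- strand != "-"   # "." treated as "+"
  relation[right_of_gene & plus_like] <- "downstream"
  relation[right_of_gene & !plus_like] <- "upstream"
  relation[left_of_gene & plus_like] <- "upstream"
  relation[left_of_gene & !plus_like] <- "downstream"

  df <- data.frame(gene_id = ann$gene_id[gi], peak_id = peaks$peak_id[pi],
                   distance_bp = as.integer(dist), relation = relation,
                   gene_strand = strand, peak_chrom = peaks$chrom[pi],
                   peak_start = ps, peak_end = pe, stringsAsFactors = FALSE)
  as_pair_table(order_pair_table(df))
}

empty_pair_table <- function() {
  as_pair_table(data.frame(
    gene_id = character(), peak_id = character(),
    distance_bp = integer(), relation = character(),
    gene_strand = character(), peak_chrom = character(),
    peak_start = integer(), peak_end = integer(), stringsAsFactors = FALSE))
}

#' Pair transcription factors with peaks covering their binding sites
#'
#' A pair (TF, peak) is formed whenever the peak intersects any binding-site
#' interval recorded for that TF. TF names that do not resolve against the
#' gene ids of the data are skipped with a logged count.
#'
#' @param data a \code{paired_omics} object.
#' @param tf_sites binding sites: a data.frame with columns \code{name} (TF),
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open), e.g. from
#'   \code{\link{read_bed}}.
#' @return a \code{pair_table}; \code{relation} is always "overlap",
#'   \code{distance_bp} always 0.
#' @export
pair_by_binding_sites <- function(data, tf_sites) {
  validate_paired_omics(data)
  if (!is.data.frame(tf_sites) || nrow(tf_sites) == 0L) {
    stop_validation("empty TF binding-site table")
  }
  tf_col <- if ("name" %in% names(tf_sites)) "name" else "tf"
  if (!(tf_col %in% names(tf_sites))) {
    stop_validation("TF site table needs a 'name' (or 'tf') column")
  }
  sites <- tf_sites[tf_sites[[tf_col]] %in% data$gene_ids, , drop = FALSE]
  n_skip <- length(setdiff(unique(tf_sites[[tf_col]]), data$gene_ids))
  if (n_skip > 0L) {
    log_msg(sprintf(
      "pair_by_binding_sites: %d TF name(s) not in gene ids skipped", n_skip))
  }
  if (nrow(sites) == 0L) {
    warning("no TF binding sites resolvable against the gene ids")
    return(empty_pair_table())
  }
  peaks <- parse_peak_id(data$peak_ids)
  peaks$peak_id <- data$peak_ids
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(sites),
                                      intervals_to_granges(peaks))
  si <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  if (!length(si)) {
    warning("no TF-peak pairs found")
    return(empty_pair_table())
  }
  df <- data.frame(gene_id = sites[[tf_col]][si],
                   peak_id = peaks$peak_id[pi],
                   distance_bp = 0L, relation = "overlap",
                   gene_strand = ".",
                   peak_chrom = peaks$chrom[pi],
                   peak_start = peaks$start[pi], peak_end = peaks$end[pi],
                   stringsAsFactors = FALSE)
  as_pair_table(order_pair_table(df))
}
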