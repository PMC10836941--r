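make_annot <- function(...) {
  df <- data.frame(...)
  df$gene_id <- as.character(df$gene_id)
  df
}

test_that("feature sparsity is the exact per-group zero fraction", {
  rna <- matrix(1, 20, 3)
  rna[1:10, 1] <- 0                       # all-zero in group A
  rna[1:3, 2] <- 0                        # 3 of 10 zeros in group A
  atac <- matrix(1, 20, 2)
  data <- toy_paired(rna, atac, groups = rep(c("A", "B"), each = 10))
  rep <- feature_sparsity(data, "group")
  get <- function(f, g) rep$zero_fraction[rep$feature_id == f & rep$group == g]
  expect_identical(get("g01", "A"), 1.0)
  expect_identical(get("g02", "A"), 0.3)
  expect_identical(get("g03", "A"), 0.0)
  expect_identical(get("g01", "B"), 0.0)
  # every gene and peak covered in every group
  expect_equal(nrow(rep), (3 + 2) * 2)
  expect_error(feature_sparsity(data, "nope"), "not found",
               class = "screglink_validation_error")
})

test_that("sparsity is invariant to cell order within groups", {
  set.seed(11)
  rna <- matrix(rbinom(200, 1, 0.5) * runif(200), 20, 10)
  data <- toy_paired(rna, matrix(1, 20, 2),
                     groups = rep(c("A", "B"), each = 10))
  r1 <- feature_sparsity(data, "group")
  perm <- c(sample(1:10), sample(11:20))   # shuffle inside groups
  r2 <- feature_sparsity(reorder_cells(data, perm), "group")
  expect_equal(r1$zero_fraction, r2$zero_fraction)
})

test_that("window pairing matches the worked interval-arithmetic examples", {
  rna <- matrix(runif(12), 3, 4)
  colnames(rna) <- c("gA", "gB", "gC", "gD")
  atac <- matrix(runif(6), 3, 2)
  data <- toy_paired(rna, atac,
                     peak_ids = c("chr1:1500-1600", "chr1:2500-2600"))
  ann <- make_annot(gene_id = "gA", chrom = "chr1", start = 1000L,
                    end = 2000L, strand = "+")
  # containment at window 0: distance 0, overlap
  p0 <- pair_by_window(data, ann, window_bp = 0)
  expect_equal(nrow(p0), 1L)
  expect_equal(p0$peak_id, "chr1:1500-1600")
  expect_equal(p0$distance_bp, 0L)
  expect_equal(p0$relation, "overlap")
  # gap 500 > window 400: excluded
  p400 <- pair_by_window(data, ann, window_bp = 400)
  expect_false("chr1:2500-2600" %in% p400$peak_id)
  # gap 500 < window 600: included downstream of a + gene, distance 500
  p600 <- pair_by_window(data, ann, window_bp = 600)
  row <- p600[p600$peak_id == "chr1:2500-2600", ]
  expect_equal(row$distance_bp, 500L)
  expect_equal(row$relation, "downstream")
  # same peak is upstream for a - strand gene
  ann_m <- make_annot(gene_id = "gA", chrom = "chr1", start = 1000L,
                      end = 2000L, strand = "-")
  p600m <- pair_by_window(data, ann_m, window_bp = 600)
  expect_equal(p600m$relation[p600m$peak_id == "chr1:2500-2600"], "upstream")
})

test_that("window pairing equals the brute-force all-pairs oracle and is monotone", {
  set.seed(21)
  n_genes <- 30; n_peaks <- 150
  gene_ids <- sprintf("gene%02d", seq_len(n_genes))
  chroms <- sample(c("chr1", "chr2"), n_genes, replace = TRUE)
  gstart <- sample.int(500000L, n_genes)
  ann <- data.frame(gene_id = gene_ids, chrom = chroms, start = gstart,
                    end = gstart + sample(500:20000, n_genes),
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  pstart <- sample.int(600000L, n_peaks)
  pchrom <- sample(c("chr1", "chr2"), n_peaks, replace = TRUE)
  peak_ids <- sprintf("%s:%d-%d", pchrom, pstart, pstart + 300L)
  rna <- matrix(runif(4 * n_genes), 4, n_genes)
  colnames(rna) <- gene_ids
  data <- toy_paired(rna, matrix(runif(4 * n_peaks), 4, n_peaks),
                     peak_ids = peak_ids)
  peaks <- parse_peak_id(peak_ids)
  peaks$peak_id <- peak_ids

  prev <- NULL
  for (w in c(0L, 1000L, 100000L)) {
    got <- pair_by_window(data, ann, window_bp = w)
    oracle <- brute_force_pairs(ann, peaks, w)
    got_keys <- sort(paste(got$gene_id, got$peak_id))
    expect_identical(got_keys, sort(paste(oracle$gene_id, oracle$peak_id)),
                     info = sprintf("window %d", w))
    if (!is.null(prev)) expect_true(all(prev %in% got_keys))
    prev <- got_keys
  }
})

test_that("pair table row order is deterministic: gene, then distance", {
  rna <- matrix(runif(8), 2, 4)
  colnames(rna) <- c("gB", "gA", "gC", "gD")
  atac <- matrix(runif(6), 2, 3)
  data <- toy_paired(rna, atac,
                     peak_ids = c("chr1:5000-5100", "chr1:900-950",
                                  "chr1:1200-1300"))
  ann <- make_annot(gene_id = c("gB", "gA"), chrom = "chr1",
                    start = c(1000L, 1000L), end = c(1100L, 1100L),
                    strand = "+")
  p <- pair_by_window(data, ann, window_bp = 10000)
  expect_equal(p$gene_id, rep(c("gA", "gB"), each = 3))
  expect_true(all(diff(p$distance_bp[p$gene_id == "gA"]) >= 0))
})

test_that("degenerate pairing inputs behave as contracted", {
  data <- toy_paired(matrix(runif(4), 2, 2), matrix(runif(4), 2, 2),
                     peak_ids = c("chr9:10-20", "chr9:30-40"))
  expect_error(pair_by_window(data, data.frame(), 1000),
               "empty", class = "screglink_validation_error")
  far <- make_annot(gene_id = "g01", chrom = "chr9", start = 100000L,
                    end = 100100L, strand = "+")
  expect_warning(p <- pair_by_window(data, far, window_bp = 10),
                 "no gene-peak pairs")
  expect_s3_class(p, "pair_table")
  expect_equal(nrow(p), 0L)
})

test_that("binding-site pairing matches exhaustive intersection", {
  rna <- matrix(runif(6), 2, 3)
  colnames(rna) <- c("GATA1", "TAL1", "other")
  atac <- matrix(runif(10), 2, 5)
  pstart <- c(150L, 1000L, 2000L, 2500L, 5000L)
  peak_ids <- sprintf("chr1:%d-%d", pstart, pstart + 100L)
  data <- toy_paired(rna, atac, peak_ids = peak_ids)
  sites <- data.frame(
    chrom = "chr1",
    start = c(100L, 180L, 2450L, 9000L),
    end = c(200L, 260L, 2550L, 9100L),
    name = c("GATA1", "GATA1", "TAL1", "ABSENT"),
    stringsAsFactors = FALSE)
  expect_message(p <- pair_by_binding_sites(data, sites), "1 TF name")
  # exhaustive check
  expected <- list()
  for (s in seq_len(nrow(sites))) {
    if (!(sites$name[s] %in% colnames(rna))) next
    for (k in seq_along(pstart)) {
      if (sites$start[s] < pstart[k] + 100L && pstart[k] < sites$end[s]) {
        expected[[length(expected) + 1L]] <-
          paste(sites$name[s], peak_ids[k])
      }
    }
  }
  expect_setequal(paste(p$gene_id, p$peak_id), unique(unlist(expected)))
  expect_true(all(p$relation == "overlap"))
  expect_true(all(p$distance_bp == 0L))
})

test_that("BED reading reports malformed lines by number", {
  f <- withr::local_tempfile(lines = c(
    "track name=sites",
    "chr1\t100\t200\tGATA1\t0\t+",
    "chr1\tnotanumber\t300\tTAL1"))
  expect_error(read_bed(f), "line 3", class = "screglink_parse_error")
  f2 <- withr::local_tempfile(lines = "chr1\t100\t200\tGATA1\t0\t+")
  bed <- read_bed(f2)
  expect_equal(bed$start, 100L)
  expect_equal(bed$name, "GATA1")
})

test_that("GFF3 gene annotation converts to 0-based half-open", {
  f <- withr::local_tempfile(lines = c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=geneX;gene_id=geneX",
    "chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tID=exon1;Parent=geneX"))
  ann <- read_gene_annotation(f, format = "gff3")
  expect_equal(nrow(ann), 1L)          # exon row filtered out
  expect_equal(ann$start, 1000L)       # 1-based 1001 -> 0-based 1000
  expect_equal(ann$end, 2000L)
  expect_equal(ann$gene_id, "geneX")
})
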