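# Genomic interval plumbing. Internal convention: 0-based half-open
# [start, end). BED input is already in this convention; GFF3/GTF (1-based
# closed) is converted on read.

#' Parse a coordinate-encoded peak id
#'
#' Accepts the two common dialects \code{"chr1:100-200"} and
#' \code{"chr1-100-200"}. Coordinates are returned in the package's internal
#' 0-based half-open convention, i.e. exactly as encoded.
#'
#' @param peak_id character vector of peak ids.
#' @return a data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (always \code{"."}), one row per id.
#' @export
parse_peak_id <- function(peak_id) {
  peak_id <- as.character(peak_id)
  m <- regmatches(peak_id,
                  regexec("^(.+?)[:\\-](\\d+)-(\\d+)$", peak_id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop_parse("cannot parse peak id(s): %s",
               paste(utils::head(peak_id[bad], 5L), collapse = ", "))
  }
  chrom <- vapply(m, `[`, "", 2L)
  start <- as.integer(vapply(m, `[`, "", 3L))
  end <- as.integer(vapply(m, `[`, "", 4L))
  if (any(end <= start)) {
    stop_parse("peak id(s) with end <= start: %s",
               paste(utils::head(peak_id[end <= start], 5L), collapse = ", "))
  }
  data.frame(chrom = chrom, start = start, end = end, strand = ".",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a gene annotation into an interval table
#'
#' GFF3/GTF files are read with \pkg{rtracklayer} and converted from 1-based
#' closed to the internal 0-based half-open convention; only rows of type
#' \code{gene} are kept (all rows if no \code{type} column matches). A plain
#' BED file (>= 4 columns, name column = gene id) is read as-is.
#'
#' @param path annotation file (.gff/.gff3/.gtf/.bed).
#' @param format one of \code{"auto"}, \code{"gff3"}, \code{"gtf"},
#'   \code{"bed"}.
#' @param id_key attribute key holding the gene id for GFF3/GTF; the first
#'   of the given keys found is used.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gff3", "gtf", "bed"),
                                 id_key = c("gene_id", "ID", "Name")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("annotation file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gtf = "gtf", gff = "gff3",
                     gff3 = "gff3",
                     stop_io("cannot guess annotation format of %s", path))
  }
  if (format == "bed") {
    bed <- read_bed(path)
    return(data.frame(gene_id = bed$name, chrom = bed$chrom,
                      start = bed$start, end = bed$end, strand = bed$strand,
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc) && any(mc$type == "gene")) {
    gr <- gr[mc$type == "gene"]
    mc <- S4Vectors::mcols(gr)
  }
  key <- id_key[id_key %in% names(mc)][1]
  if (is.na(key) || is.null(key)) {
    stop_parse("none of the id keys (%s) found in %s",
               paste(id_key, collapse = ", "), path)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(gene_id = as.character(mc[[key]]),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,  # 1-based closed -> 0-based half-open
             end = BiocGenerics::end(gr),
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a BED file (at least 4 columns)
#'
#' Hand-rolled reader so malformed lines can be reported with their line
#' number. Columns beyond BED6 are ignored; missing score/strand default to
#' \code{0} and \code{"."}.
#'
#' @param path BED file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{score}, \code{strand} (0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_io("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  rows <- which(keep)
  for (k in seq_along(rows)) {
    i <- rows[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) {
      stop_parse("malformed BED line %d in %s: fewer than 4 fields", i, path)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0L || end <= start) {
      stop_parse("malformed BED line %d in %s: bad coordinates '%s'-'%s'",
                 i, path, f[2], f[3])
    }
    strand <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "."
    score <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else 0
    out[[k]] <- data.frame(chrom = f[1], start = start, end = end,
                           name = f[4], score = if (is.na(score)) 0 else score,
                           strand = strand, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Convert an internal 0-based half-open interval table to GRanges
# (1-based closed), clamping starts at 1.
intervals_to_granges <- function(df, pad = 0L) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = pmax(df$start - pad + 1L, 1L),
                              end = df$end + pad))
}
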