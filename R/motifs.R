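# JASPAR position-frequency-matrix to Homer motif-file conversion.

#' Read JASPAR PFM records
#'
#' Parses JASPAR-style position frequency matrices: an optional
#' \code{">ID<TAB>name"} header followed by four count rows (A, C, G, T),
#' with or without the \code{"A [ ... ]"} decoration. Multiple records per
#' file are supported.
#'
#' @param path PFM text file.
#' @return a named list of 4 x width numeric count matrices (rows A, C, G,
#'   T); names are taken from the headers or generated as \code{motif_1} etc.
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) stop_io("PFM file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  motifs <- list()
  cur_name <- NULL
  cur_rows <- list()
  flush <- function() {
    if (!length(cur_rows)) return()
    if (length(cur_rows) != 4L) {
      stop_parse("PFM record '%s' in %s has %d count rows, expected 4",
                 cur_name %||% "?", path, length(cur_rows))
    }
    w <- unique(vapply(cur_rows, length, 1L))
    if (length(w) != 1L) {
      stop_parse("PFM record '%s' in %s has ragged rows",
                 cur_name %||% "?", path)
    }
    m <- do.call(rbind, cur_rows)
    rownames(m) <- c("A", "C", "G", "T")
    nm <- cur_name %||% sprintf("motif_%d", length(motifs) + 1L)
    motifs[[nm]] <<- m
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur_rows <- list()
      f <- strsplit(sub("^>", "", ln), "[\t ]+")[[1]]
      cur_name <- paste(f[nzchar(f)], collapse = "_")
    } else {
      body <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
      if (any(is.na(vals)) || !length(vals)) {
        stop_parse("unparseable PFM count row in %s: '%s'", path, ln)
      }
      cur_rows[[length(cur_rows) + 1L]] <- vals
    }
  }
  flush()
  if (!length(motifs)) stop_parse("no PFM records found in %s", path)
  motifs
}

#' Convert JASPAR PFMs to a Homer motif file
#'
#' Counts are turned into per-position base probabilities with a
#' pseudocount: \code{p = (count + pseudocount) / (total + 4 * pseudocount)}.
#' The detection threshold written in each header is
#' \code{threshold_fraction} times the maximum attainable log-odds score of
#' the motif against a uniform background, i.e.
#' \code{threshold_fraction * sum_pos log2(max_p / 0.25)}.
#'
#' @param pfm_path JASPAR PFM text file (see \code{\link{read_jaspar_pfm}}).
#' @param out_path output Homer .motif file.
#' @param pseudocount positive pseudocount added to every count; default 0.5.
#' @param threshold_fraction fraction in (0, 1] of the maximum log-odds
#'   score used as detection threshold; default 0.8.
#' @return invisibly, a data.frame with one row per motif (\code{name},
#'   \code{consensus}, \code{threshold}, \code{width}).
#' @export
jaspar_to_homer <- function(pfm_path, out_path, pseudocount = 0.5,
                            threshold_fraction = 0.8) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop_validation("'pseudocount' must be > 0")
  }
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1) {
    stop_validation("'threshold_fraction' must be in (0, 1]")
  }
  motifs <- read_jaspar_pfm(pfm_path)
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  info <- data.frame(name = character(), consensus = character(),
                     threshold = numeric(), width = integer(),
                     stringsAsFactors = FALSE)
  for (nm in names(motifs)) {
    counts <- motifs[[nm]]
    totals <- colSums(counts)
    probs <- sweep(counts + pseudocount, 2, totals + 4 * pseudocount, "/")
    max_p <- apply(probs, 2, max)
    threshold <- threshold_fraction * sum(log2(max_p / 0.25))
    consensus <- paste(bases[apply(probs, 2, which.max)], collapse = "")
    out <- c(out,
             sprintf(">%s\t%s\t%.6f", consensus, nm, threshold),
             apply(probs, 2, function(p) paste(sprintf("%.10f", p),
                                               collapse = "\t")))
    info <- rbind(info, data.frame(name = nm, consensus = consensus,
                                   threshold = threshold,
                                   width = ncol(counts),
                                   stringsAsFactors = FALSE))
  }
  writeLines(out, out_path, sep = "\n")
  invisible(info)
}
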