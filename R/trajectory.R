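# Trajectory regulation dynamics: pseudotime binning of the per-cell index,
# detection of highly variable (dynamic) pairs along a path.

#' Bin the correlation strength along a trajectory
#'
#' Restricts the cells to those whose group lies on the given path and whose
#' pseudotime is present, orders them by pseudotime, partitions them into
#' \code{n_bins} bins (equal cell count or equal pseudotime width), and
#' averages each pair's per-cell correlation strength within each bin. The
#' per-bin cell-type composition (occupancy) is recorded alongside.
#'
#' @param lc a \code{local_corr} object.
#' @param data the \code{paired_omics} the index was computed on.
#' @param path ordered character vector of group labels defining the
#'   trajectory (e.g. \code{c("HSC", "5", "7", "EryP")}).
#' @param n_bins number of pseudotime bins (>= 3); default 50.
#' @param binning \code{"equal_count"} (default; bins hold equally many
#'   cells, avoiding empty bins) or \code{"equal_width"} (equal pseudotime
#'   span; errors if a bin ends up empty).
#' @param group_key column of \code{data$cell_meta} holding the group
#'   labels; default \code{"group"}.
#' @param pseudotime_key column holding pseudotime; default
#'   \code{"pseudotime"}.
#' @return an object of class \code{trajectory_curves}: list with
#'   \code{curve} (pair x bin matrix of binned mean L), \code{bins}
#'   (data.frame of bin boundaries, centers and sizes), \code{occupancy}
#'   (bin x group proportions, rows summing to 1), \code{path},
#'   \code{binning}, and empty slots \code{variability}/\code{dynamic_mask}
#'   filled by \code{\link{detect_dynamic}}.
#' @export
trajectory_curves <- function(lc, data, path, n_bins = 50L,
                              binning = c("equal_count", "equal_width"),
                              group_key = "group",
                              pseudotime_key = "pseudotime") {
  binning <- match.arg(binning)
  if (n_bins < 3L) stop_validation("'n_bins' must be >= 3")
  meta <- data$cell_meta
  for (k in c(group_key, pseudotime_key)) {
    if (!(k %in% names(meta))) {
      stop_validation("column '%s' not found in cell_meta", k)
    }
  }
  grp <- as.character(meta[[group_key]])
  pt <- as.numeric(meta[[pseudotime_key]])
  keep <- which(grp %in% path & !is.na(pt))
  if (length(keep) < n_bins) {
    stop_validation("only %d cells on the path, need >= n_bins = %d",
                    length(keep), n_bins)
  }
  ord <- keep[order(pt[keep])]
  m <- length(ord)

  if (binning == "equal_count") {
    sizes <- diff(round(seq(0, m, length.out = n_bins + 1)))
    bin_of <- rep(seq_len(n_bins), times = sizes)
  } else {
    breaks <- seq(min(pt[ord]), max(pt[ord]), length.out = n_bins + 1)
    bin_of <- findInterval(pt[ord], breaks, rightmost.closed = TRUE,
                           all.inside = TRUE)
    if (length(unique(bin_of)) < n_bins) {
      stop_validation(paste0(
        "equal_width binning produced empty bin(s); ",
        "use binning = 'equal_count' or fewer bins"))
    }
  }
  Lsub <- lc$L[ord, , drop = FALSE]
  sums <- rowsum(Lsub, bin_of, reorder = TRUE)
  counts <- as.vector(table(bin_of))
  curve <- t(sums / counts)                       # pair x bin

  glev <- path
  occ <- t(vapply(seq_len(n_bins), function(b) {
    tab <- table(factor(grp[ord][bin_of == b], levels = glev))
    as.numeric(tab) / sum(tab)
  }, numeric(length(glev))))
  colnames(occ) <- glev

  ptb <- vapply(seq_len(n_bins), function(b) {
    v <- pt[ord][bin_of == b]
    c(min(v), max(v), mean(v))
  }, numeric(3))
  bins <- data.frame(bin = seq_len(n_bins), t_lo = ptb[1, ], t_hi = ptb[2, ],
                     t_center = ptb[3, ], n_cells = counts)

  structure(list(curve = curve, bins = bins, occupancy = occ, path = path,
                 binning = binning, variability = NULL, dynamic_mask = NULL,
                 pair_key = colnames(lc$L), selection = NULL),
            class = "trajectory_curves")
}

#' Detect dynamic gene-peak pairs along the trajectory
#'
#' Scores each pair's variability as the standard deviation of its binned
#' mean correlation strength across bins (raw binned means; no smoothing is
#' applied before scoring), then selects highly variable pairs either by a
#' threshold rule (\code{variability > mean + k * sd} over pairs) or as the
#' top \code{ceiling(k)} pairs.
#'
#' @param curves a \code{trajectory_curves} object.
#' @param method \code{"sd_threshold"} (default) or \code{"top_n"}.
#' @param k threshold multiplier (sd_threshold; default 1.0) or number of
#'   pairs (top_n; must be > 0).
#' @return the \code{trajectory_curves} with \code{variability} and
#'   \code{dynamic_mask} filled.
#' @export
detect_dynamic <- function(curves, method = c("sd_threshold", "top_n"),
                           k = 1.0) {
  method <- match.arg(method)
  if (!inherits(curves, "trajectory_curves")) {
    stop_validation("'curves' must be a trajectory_curves object")
  }
  vab <- apply(curves$curve, 1, stats::sd)
  if (method == "top_n") {
    if (k <= 0) stop_validation("'k' must be > 0 for top_n selection")
    ntop <- min(ceiling(k), length(vab))
    mask <- rep(FALSE, length(vab))
    mask[order(vab, decreasing = TRUE)[seq_len(ntop)]] <- TRUE
  } else {
    mask <- vab > mean(vab) + k * stats::sd(vab)
  }
  curves$variability <- stats::setNames(vab, rownames(curves$curve))
  curves$dynamic_mask <- stats::setNames(mask, rownames(curves$curve))
  curves$selection <- list(method = method, k = k)
  log_msg(sprintf("detect_dynamic: %d of %d pairs selected (%s, k = %g)",
                  sum(mask), length(mask), method, k))
  curves
}

#' @export
print.trajectory_curves <- function(x, ...) {
  cat(sprintf("trajectory_curves: %d pairs x %d %s bins, path %s\n",
              nrow(x$curve), nrow(x$bins), x$binning,
              paste(x$path, collapse = " - ")))
  if (!is.null(x$dynamic_mask)) {
    cat(sprintf("  %d dynamic pair(s) selected (%s, k = %g)\n",
                sum(x$dynamic_mask), x$selection$method, x$selection$k))
  }
  invisible(x)
}

#' Write trajectory curves (TSV matrix + JSON bin metadata)
#' @param curves a \code{trajectory_curves} object.
#' @param prefix output path prefix; writes \code{<prefix>_curves.tsv},
#'   \code{<prefix>_bins.json} and, if selection was run,
#'   \code{<prefix>_variability.tsv}.
#' @return invisibly, the paths written.
#' @export
write_trajectory_curves <- function(curves, prefix) {
  ctab <- data.frame(pair_key = rownames(curves$curve),
                     curves$curve, check.names = FALSE)
  colnames(ctab)[-1] <- sprintf("bin%02d", seq_len(ncol(curves$curve)))
  p1 <- paste0(prefix, "_curves.tsv")
  write_tsv(ctab, p1)
  p2 <- paste0(prefix, "_bins.json")
  jsonlite::write_json(
    list(path = curves$path, binning = curves$binning,
         bins = curves$bins, occupancy = as.data.frame(curves$occupancy)),
    p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(p1, p2)
  if (!is.null(curves$variability)) {
    p3 <- paste0(prefix, "_variability.tsv")
    write_tsv(data.frame(pair_key = names(curves$variability),
                         variability = unname(curves$variability),
                         dynamic = unname(curves$dynamic_mask)), p3)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
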