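# Static figure emitters (PNG/PDF/SVG by file extension, base graphics).
# All functions are file-emitting only; figure content is meant for visual
# inspection, so tests check structural properties (file exists, expected
# pixel dimensions), not pixels.

open_device <- function(path, width = 8, height = 4, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width * dpi,
                              height = height * dpi, res = dpi),
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         stop_validation("unsupported figure format '.%s' (png/pdf/svg)", ext))
  invisible(NULL)
}

# diverging blue-white-red ramp for L, clipped to limits
l_colors <- function(v, limits) {
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(256)
  v <- pmin(pmax(v, limits[1]), limits[2])
  pal[1 + round(255 * (v - limits[1]) / diff(limits))]
}

seq_colors <- function(v) {
  pal <- grDevices::hcl.colors(256, "viridis")
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  pal[1 + round(255 * (v - rng[1]) / diff(rng))]
}

check_color_limits <- function(limits) {
  if (length(limits) != 2L || limits[1] >= limits[2]) {
    stop_validation("color limits must be an increasing pair")
  }
  limits
}

#' Embedding triptych: expression, accessibility, correlation strength
#'
#' Three scatter panels on the 2-D embedding, colored by the pair's gene
#' expression, peak accessibility, and per-cell correlation strength
#' (clipped to \code{color_limits}; the recommended display range for L is
#' [-1, 1] even though extreme values can exceed it).
#'
#' @param data a \code{paired_omics} with an embedding.
#' @param lc a \code{local_corr} object.
#' @param pair_key the \code{"gene|peak"} column key to display.
#' @param path output figure file (.png/.pdf/.svg).
#' @param color_limits L color range; default c(-1, 1).
#' @param dpi raster resolution; default 150.
#' @return \code{path}, invisibly.
#' @export
plot_embedding_triptych <- function(data, lc, pair_key, path,
                                    color_limits = c(-1, 1), dpi = 150) {
  if (is.null(data$embedding)) {
    stop_validation("data has no embedding; cannot draw the triptych")
  }
  check_color_limits(color_limits)
  if (!(pair_key %in% colnames(lc$L))) {
    stop_validation("pair key '%s' not found in the local_corr result",
                    pair_key)
  }
  ids <- strsplit(pair_key, "|", fixed = TRUE)[[1]]
  x <- as.numeric(data$rna[, match(ids[1], data$gene_ids)])
  y <- as.numeric(data$atac[, match(ids[2], data$peak_ids)])
  l <- lc$L[, pair_key]
  open_device(path, width = 12, height = 4, dpi = dpi)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 3), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  emb <- data$embedding
  graphics::plot(emb, col = seq_colors(x), pch = 16, cex = 0.4,
                 main = paste0(ids[1], " expression"), xlab = "", ylab = "")
  graphics::plot(emb, col = seq_colors(y), pch = 16, cex = 0.4,
                 main = paste0(ids[2], " accessibility"), xlab = "", ylab = "")
  graphics::plot(emb, col = l_colors(l, color_limits), pch = 16, cex = 0.4,
                 main = "correlation strength L", xlab = "", ylab = "")
  invisible(path)
}

#' Heatmap of marker correlation strengths
#'
#' Rows are cells ordered by group, columns are flagged marker pairs ordered
#' by their owning group; color is the correlation strength clipped to
#' \code{color_limits}.
#'
#' @param lc a \code{local_corr} object.
#' @param markers a \code{marker_result}; only rows with
#'   \code{is_marker == TRUE} are drawn.
#' @param groups group label per cell.
#' @param path output figure file.
#' @param color_limits color range for L; default c(-1, 1).
#' @param dpi raster resolution.
#' @return \code{path}, invisibly.
#' @export
plot_marker_heatmap <- function(lc, markers, groups, path,
                                color_limits = c(-1, 1), dpi = 150) {
  check_color_limits(color_limits)
  mk <- markers[markers$is_marker, , drop = FALSE]
  if (nrow(mk) == 0L) stop_validation("no flagged markers to draw")
  groups <- resolve_groups(lc, groups)
  mk <- mk[order(match(mk$group, levels(groups)), mk$q_value), , drop = FALSE]
  keys <- unique(mk$pair_key)
  cell_ord <- order(groups)
  M <- lc$L[cell_ord, keys, drop = FALSE]
  M <- pmin(pmax(M, color_limits[1]), color_limits[2])
  open_device(path, width = 7, height = 6, dpi = dpi)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(256)
  graphics::image(x = seq_len(ncol(M)), y = seq_len(nrow(M)), z = t(M)[, rev(seq_len(nrow(M))), drop = FALSE],
                  zlim = color_limits, col = pal, xlab = "marker pairs",
                  ylab = "cells (by group)", main = "regulatory markers",
                  axes = FALSE)
  graphics::box()
  # group separators
  sep <- cumsum(table(groups))
  graphics::abline(h = nrow(M) - sep[-length(sep)] + 0.5, col = "black")
  invisible(path)
}

#' Volcano plot of marker tests for one group
#'
#' x = difference of group means of L, y = -log10(BH-adjusted q value),
#' with the significance and effect thresholds drawn.
#'
#' @param markers a \code{marker_result}.
#' @param group group label to display.
#' @param path output figure file.
#' @param alpha significance threshold line; default 0.05.
#' @param min_delta effect threshold lines; default 0 (omitted).
#' @param dpi raster resolution.
#' @return \code{path}, invisibly.
#' @export
plot_volcano <- function(markers, group, path, alpha = 0.05, min_delta = 0,
                         dpi = 150) {
  mk <- markers[markers$group == group, , drop = FALSE]
  if (nrow(mk) == 0L) {
    stop_validation("group '%s' not present in the marker result", group)
  }
  open_device(path, width = 5, height = 5, dpi = dpi)
  on.exit(grDevices::dev.off())
  y <- -log10(pmax(mk$q_value, 1e-300))
  cols <- ifelse(mk$is_marker, "#B2182B", "grey50")
  graphics::plot(mk$delta_L, y, pch = 16, cex = 0.6, col = cols,
                 xlab = "delta L (group - rest)", ylab = "-log10(q)",
                 main = sprintf("regulatory markers: %s", group))
  graphics::abline(h = -log10(alpha), lty = 2)
  if (min_delta > 0) graphics::abline(v = c(-1, 1) * min_delta, lty = 3)
  invisible(path)
}

# Gaussian kernel smoothing over bin index (bandwidth in bins); display only
smooth_curve <- function(v, bw = 1) {
  b <- seq_along(v)
  vapply(b, function(i) {
    w <- exp(-((b - i)^2) / (2 * bw^2))
    sum(w * v) / sum(w)
  }, numeric(1))
}

#' Trajectory regulation curves with cell-type occupancy bar
#'
#' Gray lines are the per-pair binned regulation curves (Gaussian-smoothed
#' over the bin index for display only); colored lines are SOM module
#' prototype curves when \code{modules} is supplied (curves are then drawn
#' z-normalized, matching the prototype scale). A stacked bar under the
#' curves shows the cell-type composition of each time bin.
#'
#' @param curves a \code{trajectory_curves} object.
#' @param modules optional \code{som_modules}; restricts the gray lines to
#'   the clustered dynamic pairs and overlays prototypes.
#' @param path output figure file.
#' @param dpi raster resolution.
#' @return \code{path}, invisibly.
#' @export
plot_dynamic_curves <- function(curves, modules = NULL, path, dpi = 150) {
  B <- ncol(curves$curve)
  if (B < 2L) stop_validation("cannot draw curves with a single bin")
  open_device(path, width = 7, height = 6, dpi = dpi)
  on.exit(grDevices::dev.off())
  layout_old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(layout_old), add = TRUE)
  graphics::layout(matrix(1:2, ncol = 1), heights = c(4, 1.2))
  graphics::par(mar = c(1, 4, 2, 1))
  if (is.null(modules)) {
    M <- curves$curve
    ylab <- "binned mean L"
  } else {
    keys <- names(modules$module_id)
    M <- curves$curve[keys, , drop = FALSE]
    M <- t(apply(M, 1, function(v) (v - mean(v)) / stats::sd(v)))
    ylab <- "normalized binned L"
  }
  Ms <- t(apply(M, 1, smooth_curve))
  graphics::matplot(t(Ms), type = "l", lty = 1, col = grDevices::adjustcolor("grey40", 0.35),
                    xlab = "", ylab = ylab, main = "regulation dynamics",
                    xaxt = "n")
  if (!is.null(modules)) {
    cols <- grDevices::hcl.colors(nrow(modules$prototypes), "Dark 3")
    for (u in seq_len(nrow(modules$prototypes))) {
      graphics::lines(smooth_curve(modules$prototypes[u, ]), col = cols[u],
                      lwd = 3)
    }
    graphics::legend("topleft", legend = paste("module", seq_along(cols)),
                     col = cols, lwd = 3, bty = "n", cex = 0.8)
  }
  graphics::par(mar = c(3, 4, 0.5, 1))
  occ <- t(curves$occupancy)
  gcols <- grDevices::hcl.colors(nrow(occ), "Set 2")
  graphics::barplot(occ, col = gcols, border = NA, space = 0,
                    names.arg = seq_len(B), ylab = "occupancy",
                    cex.names = 0.6, las = 1)
  invisible(path)
}
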