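# Regulatory-marker detection between cell groups on the per-cell
# correlation strength matrix, plus the plain-Pearson baseline.

# rank-sum test guarded against fully tied columns
safe_rank_test <- function(a, b, test = "wilcox") {
  if (stats::sd(c(a, b)) == 0) {
    # identical constant in both groups: no signal by construction
    return(c(statistic = length(a) * length(b) / 2, p_value = 1))
  }
  if (test == "wilcox") {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  } else {
    ht <- tryCatch(stats::t.test(a, b),
                   error = function(e) list(statistic = 0, p.value = 1))
  }
  p <- ht$p.value
  if (is.na(p)) p <- 1
  c(statistic = unname(ht$statistic), p_value = p)
}

markers_one_comparison <- function(L, idx_a, idx_b, group_label,
                                   min_delta, alpha, test) {
  res <- t(apply(L, 2, function(v) safe_rank_test(v[idx_a], v[idx_b], test)))
  delta <- colMeans(L[idx_a, , drop = FALSE]) -
    colMeans(L[idx_b, , drop = FALSE])
  q <- stats::p.adjust(res[, "p_value"], method = "BH")
  data.frame(group = group_label, pair_key = colnames(L),
             delta_L = unname(delta),
             statistic = unname(res[, "statistic"]),
             p_value = unname(res[, "p_value"]), q_value = unname(q),
             n_group = length(idx_a), n_rest = length(idx_b),
             is_marker = unname(q < alpha & abs(delta) >= min_delta),
             stringsAsFactors = FALSE, row.names = NULL)
}

attach_pair_ids <- function(df, pairs) {
  key <- pair_key(pairs)
  m <- match(df$pair_key, key)
  df$gene_id <- pairs$gene_id[m]
  df$peak_id <- pairs$peak_id[m]
  df <- df[, c("group", "gene_id", "peak_id", "pair_key", "delta_L",
               "statistic", "p_value", "q_value", "n_group", "n_rest",
               "is_marker")]
  class(df) <- c("marker_result", "data.frame")
  df
}

resolve_groups <- function(lc, groups) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(lc$L)) {
    stop_validation("'groups' has length %d but L has %d cells",
                    length(groups), nrow(lc$L))
  }
  groups
}

#' One-vs-rest regulatory marker detection
#'
#' For every group, each pair's per-cell correlation strengths in the group
#' are compared against all remaining cells with a two-sided Wilcoxon
#' rank-sum test (t-test available as an option); p-values are
#' Benjamini-Hochberg adjusted across pairs within each group's family. A
#' pair is flagged as a marker of a group when \code{q_value < alpha} and
#' \code{|delta_L| >= min_delta}.
#'
#' Note that the per-cell index is smoothed over the neighborhood graph, so
#' values of nearby cells are not independent; with strongly smoothing
#' graphs the tests grow anticonservative for groups that are contiguous on
#' the graph.
#'
#' @param lc a \code{local_corr} object.
#' @param groups group label per cell (factor or vector of length n).
#' @param min_delta minimal absolute difference of group means of L required
#'   to flag a marker; default 0 (the scale of L depends on the graph
#'   smoothing, so no universal floor is imposed).
#' @param alpha BH-adjusted significance level; default 0.05.
#' @param test "wilcox" (default) or "t".
#' @return a \code{marker_result} data.frame with one row per (group, pair).
#'   Groups with fewer than 3 cells are skipped with a warning.
#' @export
find_all_markers <- function(lc, groups, min_delta = 0, alpha = 0.05,
                             test = c("wilcox", "t")) {
  test <- match.arg(test)
  groups <- resolve_groups(lc, groups)
  lv <- levels(droplevels(groups))
  if (length(lv) < 2L) stop_validation("need at least 2 groups")
  out <- list()
  for (g in lv) {
    idx_a <- which(groups == g)
    if (length(idx_a) < 3L) {
      warning(sprintf("group '%s' has < 3 cells; skipped", g))
      next
    }
    out[[g]] <- markers_one_comparison(lc$L, idx_a, which(groups != g),
                                       g, min_delta, alpha, test)
  }
  if (!length(out)) stop_validation("no group with >= 3 cells")
  attach_pair_ids(do.call(rbind, out), lc$pairs)
}

#' Marker detection between two named groups or conditions
#'
#' Like \code{\link{find_all_markers}} but comparing two explicit groups;
#' \code{delta_L} is mean(L in \code{group_a}) - mean(L in \code{group_b}),
#' so swapping the groups negates \code{delta_L} and leaves p-values
#' unchanged.
#'
#' @inheritParams find_all_markers
#' @param group_a,group_b the two group labels to compare (must differ).
#' @return a \code{marker_result} data.frame (group column = \code{group_a}).
#' @export
find_markers <- function(lc, groups, group_a, group_b, min_delta = 0,
                         alpha = 0.05, test = c("wilcox", "t")) {
  test <- match.arg(test)
  if (identical(group_a, group_b)) {
    stop_validation("'group_a' and 'group_b' must differ")
  }
  groups <- resolve_groups(lc, groups)
  for (g in c(group_a, group_b)) {
    if (!(g %in% groups)) stop_validation("group '%s' not present", g)
    if (sum(groups == g) < 3L) {
      stop_validation("group '%s' has fewer than 3 cells", g)
    }
  }
  df <- markers_one_comparison(lc$L, which(groups == group_a),
                               which(groups == group_b),
                               group_a, min_delta, alpha, test)
  attach_pair_ids(df, lc$pairs)
}

#' @export
print.marker_result <- function(x, ...) {
  cat(sprintf("marker_result: %d tests, %d flagged markers across %d group(s)\n",
              nrow(x), sum(x$is_marker), length(unique(x$group))))
  invisible(x)
}

#' Plain Pearson correlation baseline per pair
#'
#' The conventional alternative to the per-cell index: a single Pearson's r
#' per gene-peak pair, over all cells or within each group. Zero-variance
#' pairs yield \code{NA} with a warning.
#'
#' @param data a \code{paired_omics} object.
#' @param pairs a \code{pair_table}.
#' @param groups optional group label per cell; when given, r is computed
#'   within each group and a data.frame (group, pair_key, r) is returned.
#' @return named numeric vector of r (or a data.frame when \code{groups}
#'   is given).
#' @export
pearson_baseline <- function(data, pairs, groups = NULL) {
  validate_paired_omics(data)
  gi <- match(pairs$gene_id, data$gene_ids)
  pi <- match(pairs$peak_id, data$peak_ids)
  if (anyNA(gi) || anyNA(pi)) {
    stop_validation("pair table contains ids not present in the data")
  }
  r_for <- function(cells) {
    X <- as.matrix(data$rna[cells, gi, drop = FALSE])
    Y <- as.matrix(data$atac[cells, pi, drop = FALSE])
    r <- vapply(seq_len(ncol(X)), function(j) {
      if (stats::sd(X[, j]) == 0 || stats::sd(Y[, j]) == 0) NA_real_
      else stats::cor(X[, j], Y[, j])
    }, numeric(1))
    if (anyNA(r)) warning(sprintf("%d zero-variance pair(s) yielded NA",
                                  sum(is.na(r))))
    stats::setNames(r, pair_key(pairs))
  }
  if (is.null(groups)) return(r_for(seq_len(nrow(data$rna))))
  groups <- as.factor(groups)
  out <- lapply(levels(groups), function(g) {
    data.frame(group = g, pair_key = pair_key(pairs),
               r = unname(r_for(which(groups == g))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
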