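# Core module: the per-cell gene-peak correlation strength index.
#
# For a gene vector x and peak vector y over n cells, the index of cell i is
#
#   L_i = n * (lag(x)_i - mean(x)) * (lag(y)_i - mean(y)) /
#         ( sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)) )
#
# where lag() is the spatial lag over the row-stochastic weight matrix W.
# Writing Zx, Zy for the population-z-scored (ddof 0) columns, this is
# exactly the Hadamard product (W Zx) o (W Zy): with rows of W summing to 1,
# W Zx = (W x - mean(x)) / sd_pop(x), and the denominator above equals
# n * sd_pop(x) * sd_pop(y). The algebra holds only for ddof 0; sample
# (ddof 1) z-scoring would break the identity between the two forms.
#
# The global per-pair index is the average of L over cells, a Lee's-L-style
# global bivariate spatial association; with W = I it reduces exactly to
# Pearson's r.

# population (ddof 0) z-scoring of dense matrix columns
zscore_pop <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  ctr <- sweep(M, 2, mu, "-")
  sd_pop <- sqrt(colSums(ctr^2) / n)
  list(Z = sweep(ctr, 2, sd_pop, "/"), sd = sd_pop, mu = mu)
}

#' Per-cell gene-peak correlation strength
#'
#' Computes the cell x pair matrix L of neighborhood-inferred correlation
#' strengths for the given gene-peak pairs, plus the per-pair global index
#' (column means of L). Computation is vectorized and chunked over pairs;
#' the result is bitwise-independent of \code{chunk_size}.
#'
#' Pairs whose gene or peak has zero variance across cells are dropped with
#' a warning. With \code{zero_dropouts = TRUE}, entries of L are set to 0
#' wherever the raw (pre-z-score) gene or peak value of that cell is exactly
#' 0: after centering and scaling, dropout zeros become spurious negative
#' values that would otherwise bias the index. The stored
#' \code{global_index} is always the pre-zeroing column mean.
#'
#' @param data a \code{paired_omics} object.
#' @param pairs a \code{pair_table} (or data.frame with \code{gene_id},
#'   \code{peak_id}) defining the pairs; its row order defines the column
#'   order of L.
#' @param W row-stochastic weight matrix from \code{\link{build_weights}};
#'   if \code{NULL}, built from \code{data$connectivities} with self weight 1.
#' @param zero_dropouts zero the index at raw-dropout entries; default
#'   \code{FALSE}.
#' @param chunk_size number of pairs processed per chunk; default 1000.
#' @return an object of class \code{local_corr}: list with \code{L} (dense
#'   cell x pair matrix, columns keyed \code{"gene|peak"}), \code{pairs}
#'   (the retained pair table), \code{global_index} (named numeric),
#'   \code{zeroed_dropouts}, \code{n_dropped}.
#' @export
local_correlation <- function(data, pairs, W = NULL, zero_dropouts = FALSE,
                              chunk_size = 1000L) {
  validate_paired_omics(data)
  if (!is.data.frame(pairs) || nrow(pairs) == 0L) {
    stop_validation("'pairs' must be a nonempty pair table")
  }
  if (chunk_size < 1L) stop_validation("'chunk_size' must be >= 1")
  if (is.null(W)) W <- build_weights(data$connectivities)
  check_weight_matrix(W)
  n <- length(data$cell_ids)
  if (nrow(W) != n) {
    stop_validation("W is %d x %d but there are %d cells", nrow(W), ncol(W), n)
  }
  gi <- match(pairs$gene_id, data$gene_ids)
  pi <- match(pairs$peak_id, data$peak_ids)
  if (anyNA(gi)) {
    stop_validation("pair table gene id(s) not in data: %s",
                    paste(utils::head(pairs$gene_id[is.na(gi)], 5), collapse = ", "))
  }
  if (anyNA(pi)) {
    stop_validation("pair table peak id(s) not in data: %s",
                    paste(utils::head(pairs$peak_id[is.na(pi)], 5), collapse = ", "))
  }

  # drop degenerate pairs (zero population variance in either member)
  gvar <- col_var_pop(data$rna, unique(gi))
  pvar <- col_var_pop(data$atac, unique(pi))
  bad <- gvar[as.character(gi)] == 0 | pvar[as.character(pi)] == 0
  if (all(bad)) stop_validation("all pairs are degenerate (zero variance)")
  if (any(bad)) {
    warning(sprintf("dropping %d degenerate pair(s) with zero variance",
                    sum(bad)))
    pairs <- pairs[!bad, , drop = FALSE]
    gi <- gi[!bad]; pi <- pi[!bad]
  }
  p <- nrow(pairs)
  keys <- pair_key(pairs)
  L <- matrix(0, n, p, dimnames = list(data$cell_ids, keys))
  global_index <- numeric(p)
  chunks <- split(seq_len(p), ceiling(seq_len(p) / chunk_size))
  for (ch in chunks) {
    X <- as.matrix(data$rna[, gi[ch], drop = FALSE])
    Y <- as.matrix(data$atac[, pi[ch], drop = FALSE])
    Zx <- zscore_pop(X)$Z
    Zy <- zscore_pop(Y)$Z
    Lc <- as.matrix(W %*% Zx) * as.matrix(W %*% Zy)
    global_index[ch] <- colMeans(Lc)
    if (zero_dropouts) Lc[X == 0 | Y == 0] <- 0
    L[, ch] <- Lc
  }
  names(global_index) <- keys
  structure(list(L = L, pairs = as_pair_table(as.data.frame(pairs)),
                 global_index = global_index,
                 zeroed_dropouts = zero_dropouts,
                 n_dropped = sum(bad)),
            class = "local_corr")
}

# population variance of selected columns of a sparse matrix, keyed by index
col_var_pop <- function(m, idx) {
  sub <- m[, idx, drop = FALSE]
  n <- nrow(sub)
  mu <- Matrix::colMeans(sub)
  v <- Matrix::colMeans(sub^2) - mu^2
  stats::setNames(as.numeric(v), as.character(idx))
}

#' Global correlation index only
#'
#' Convenience path computing just the per-pair global index (the average
#' of the per-cell correlation strength over all cells) without retaining
#' the full L matrix in the result. Equals
#' \code{local_correlation(...)$global_index} exactly.
#'
#' @inheritParams local_correlation
#' @return named numeric vector of per-pair global indices.
#' @export
global_correlation <- function(data, pairs, W = NULL, chunk_size = 1000L) {
  lc <- local_correlation(data, pairs, W = W, zero_dropouts = FALSE,
                          chunk_size = chunk_size)
  lc$global_index
}

#' @export
print.local_corr <- function(x, ...) {
  cat(sprintf("local_corr: %d cells x %d gene-peak pairs\n",
              nrow(x$L), ncol(x$L)))
  cat(sprintf("  global index range: [%.3f, %.3f]\n",
              min(x$global_index), max(x$global_index)))
  if (isTRUE(x$zeroed_dropouts)) cat("  dropout zeroing applied\n")
  if (!is.na(x$n_dropped) && x$n_dropped > 0) {
    cat(sprintf("  %d degenerate pair(s) dropped\n", x$n_dropped))
  }
  invisible(x)
}

#' @export
summary.local_corr <- function(object, ...) {
  print(object)
  cat("global index quantiles:\n")
  print(round(stats::quantile(object$global_index,
                              c(0, 0.25, 0.5, 0.75, 1)), 4))
  invisible(object)
}

#' @export
coef.local_corr <- function(object, ...) object$global_index
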