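# Shared fixtures and independent oracles used across the suite.

# Naive per-cell evaluation of the correlation strength:
#   L_i = n (lag_x_i - xbar)(lag_y_i - ybar) / (sqrt(sum((x-xbar)^2)) sqrt(sum((y-ybar)^2)))
# computed cell by cell and pair by pair, independent of the vectorized path.
naive_local_corr <- function(X, Y, W) {
  W <- as.matrix(W)
  n <- nrow(X)
  L <- matrix(0, n, ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]; y <- Y[, j]
    xbar <- mean(x); ybar <- mean(y)
    denom <- sqrt(sum((x - xbar)^2)) * sqrt(sum((y - ybar)^2))
    for (i in seq_len(n)) {
      lag_x <- sum(W[i, ] * x)
      lag_y <- sum(W[i, ] * y)
      L[i, j] <- n * (lag_x - xbar) * (lag_y - ybar) / denom
    }
  }
  L
}

# Exhaustive all-pairs window pairing oracle over half-open intervals.
brute_force_pairs <- function(genes, peaks, window_bp) {
  out <- list()
  for (g in seq_len(nrow(genes))) {
    for (p in seq_len(nrow(peaks))) {
      if (genes$chrom[g] != peaks$chrom[p]) next
      lo <- genes$start[g] - window_bp
      hi <- genes$end[g] + window_bp
      if (peaks$start[p] < hi && lo < peaks$end[p]) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = genes$gene_id[g], peak_id = peaks$peak_id[p],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(gene_id = character(),
                                      peak_id = character()))
  df <- do.call(rbind, out)
  df[order(df$gene_id, df$peak_id), , drop = FALSE]
}

# Small fully-specified paired container: features are supplied as dense
# matrices, the graph defaults to no connectivities (W becomes identity).
toy_paired <- function(rna, atac, groups = NULL, pseudotime = NULL,
                       conn = NULL, peak_ids = NULL, embedding = NULL) {
  n <- nrow(rna)
  if (is.null(colnames(rna))) {
    colnames(rna) <- sprintf("g%02d", seq_len(ncol(rna)))
  }
  if (is.null(peak_ids)) {
    peak_ids <- sprintf("chr1:%d-%d", seq_len(ncol(atac)) * 1000L,
                        seq_len(ncol(atac)) * 1000L + 400L)
  }
  colnames(atac) <- peak_ids
  meta <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    group = if (is.null(groups)) rep(c("A", "B"), length.out = n) else groups,
    pseudotime = if (is.null(pseudotime)) seq(0, 1, length.out = n) else pseudotime,
    path = "main", stringsAsFactors = FALSE)
  if (is.null(conn)) {
    conn <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(n, n))
  }
  paired_omics(rna = rna, atac = atac, cell_meta = meta,
               connectivities = conn, embedding = embedding)
}

all_pairs_table <- function(data) {
  data.frame(gene_id = data$gene_ids,
             peak_id = data$peak_ids[seq_along(data$gene_ids)],
             distance_bp = 0L, relation = "overlap",
             stringsAsFactors = FALSE)
}

# Random kNN-graph instance for oracle tests: n cells, p pairs.
random_instance <- function(n, p, seed, k = 8) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("g%03d", seq_len(p))
  coord <- cbind(runif(n), runif(n))
  D <- as.matrix(dist(coord))
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    nb <- ord[ord != i][seq_len(k)]
    ii <- c(ii, rep(i, k)); jj <- c(jj, nb)
  }
  conn <- Matrix::sparseMatrix(i = ii, j = jj, x = runif(length(ii)),
                               dims = c(n, n))
  conn <- (conn + Matrix::t(conn)) / 2
  data <- toy_paired(pmax(X + 4, 0), pmax(Y + 4, 0), conn = conn)
  list(data = data, pairs = all_pairs_table(data))
}
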