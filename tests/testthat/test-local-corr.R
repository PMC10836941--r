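# Core index: closed-form limits, oracle equivalence, algebraic invariants.

identity_paired <- function(x, y) {
  toy_paired(matrix(x, ncol = 1), matrix(y, ncol = 1))
}

test_that("with W = identity the index reduces to z-score products", {
  data <- identity_paired(c(1, 2, 3), c(1, 2, 3))
  lc <- local_correlation(data, all_pairs_table(data))
  expect_equal(as.numeric(lc$L), c(1.5, 0, 1.5), tolerance = 1e-12)
  expect_equal(unname(lc$global_index), 1, tolerance = 1e-12)
  anti <- identity_paired(c(1, 2, 3), c(3, 2, 1))
  lc2 <- local_correlation(anti, all_pairs_table(anti))
  expect_equal(as.numeric(lc2$L), c(-1.5, 0, -1.5), tolerance = 1e-12)
  expect_equal(unname(lc2$global_index), -1, tolerance = 1e-12)
})

test_that("vectorized L equals the naive per-cell double-loop oracle", {
  for (seed in 1:2) {
    inst <- random_instance(n = 80, p = 10, seed = seed)
    W <- build_weights(inst$data$connectivities)
    lc <- local_correlation(inst$data, inst$pairs, W = W)
    oracle <- naive_local_corr(as.matrix(inst$data$rna),
                               as.matrix(inst$data$atac), W)
    expect_lt(max(abs(unname(lc$L) - oracle)), 1e-10)
    # averaging identity
    expect_lt(max(abs(colMeans(lc$L) - lc$global_index)), 1e-12)
  }
})

test_that("the index is symmetric in the two modalities", {
  inst <- random_instance(n = 60, p = 5, seed = 4)
  W <- build_weights(inst$data$connectivities)
  lc <- local_correlation(inst$data, inst$pairs, W = W)
  swapped <- toy_paired(as.matrix(inst$data$atac), as.matrix(inst$data$rna),
                        conn = inst$data$connectivities)
  colnames_sw <- data.frame(gene_id = swapped$gene_ids,
                            peak_id = swapped$peak_ids,
                            distance_bp = 0L, relation = "overlap")
  lc_sw <- local_correlation(swapped, colnames_sw, W = W)
  expect_lt(max(abs(unname(lc$L) - unname(lc_sw$L))), 1e-12)
})

test_that("positive affine rescaling of either member leaves L unchanged", {
  inst <- random_instance(n = 50, p = 4, seed = 5)
  W <- build_weights(inst$data$connectivities)
  lc <- local_correlation(inst$data, inst$pairs, W = W)
  scaled <- toy_paired(as.matrix(inst$data$rna) * 3 + 2,
                       as.matrix(inst$data$atac) * 0.5 + 7,
                       conn = inst$data$connectivities)
  lc2 <- local_correlation(scaled, all_pairs_table(scaled), W = W)
  expect_lt(max(abs(unname(lc$L) - unname(lc2$L))), 1e-10)
})

test_that("permuting cells everywhere permutes the rows of L identically", {
  inst <- random_instance(n = 40, p = 4, seed = 6)
  W <- build_weights(inst$data$connectivities)
  lc <- local_correlation(inst$data, inst$pairs, W = W)
  set.seed(1); perm <- sample(40)
  data_p <- reorder_cells(inst$data, perm)
  W_p <- build_weights(data_p$connectivities)
  lc_p <- local_correlation(data_p, inst$pairs, W = W_p)
  expect_lt(max(abs(unname(lc$L)[perm, ] - unname(lc_p$L))), 1e-10)
})

test_that("L is bitwise-independent of the chunk size", {
  inst <- random_instance(n = 60, p = 23, seed = 7)
  W <- build_weights(inst$data$connectivities)
  ref <- local_correlation(inst$data, inst$pairs, W = W, chunk_size = 1000)
  for (cs in c(1, 7)) {
    lc <- local_correlation(inst$data, inst$pairs, W = W, chunk_size = cs)
    expect_identical(lc$L, ref$L)
    expect_identical(lc$global_index, ref$global_index)
  }
})

test_that("dropout zeroing zeroes exactly the raw-zero entries, after the global mean", {
  x <- c(1, 2, 0, 4, 5)
  y <- c(2, 0, 3, 4, 5)
  data <- identity_paired(x, y)
  plain <- local_correlation(data, all_pairs_table(data))
  zeroed <- local_correlation(data, all_pairs_table(data),
                              zero_dropouts = TRUE)
  expect_true(all(zeroed$L[x == 0 | y == 0, 1] == 0))
  expect_equal(zeroed$L[x != 0 & y != 0, 1], plain$L[x != 0 & y != 0, 1])
  # global index is stored from the pre-zeroing column means
  expect_identical(zeroed$global_index, plain$global_index)
  expect_true(zeroed$zeroed_dropouts)
})

test_that("degenerate pairs are dropped with a warning, all-degenerate errors", {
  rna <- cbind(const = rep(2, 10), ok = rnorm(10) + 5)
  atac <- cbind(a = runif(10), b = runif(10))
  data <- toy_paired(pmax(rna, 0), atac)
  pairs <- data.frame(gene_id = c("const", "ok"),
                      peak_id = data$peak_ids,
                      distance_bp = 0L, relation = "overlap")
  expect_warning(lc <- local_correlation(data, pairs), "degenerate")
  expect_equal(ncol(lc$L), 1L)
  expect_equal(lc$pairs$gene_id, "ok")
  expect_equal(lc$n_dropped, 1L)
  only_bad <- pairs[1, , drop = FALSE]
  expect_error(suppressWarnings(local_correlation(data, only_bad)),
               "degenerate", class = "screglink_validation_error")
})

test_that("a malformed weight matrix is rejected", {
  inst <- random_instance(n = 10, p = 2, seed = 8)
  W_bad <- build_weights(inst$data$connectivities)
  W_bad[1, 1] <- W_bad[1, 1] + 0.5      # break row-stochasticity
  expect_error(local_correlation(inst$data, inst$pairs, W = W_bad),
               "sum to 1", class = "screglink_validation_error")
})

test_that("global_correlation equals the stored global index and Pearson under W = I", {
  set.seed(9)
  n <- 200
  X <- matrix(rnorm(n * 20) + 5, n, 20)
  Y <- matrix(rnorm(n * 20) + 5, n, 20)
  data <- toy_paired(pmax(X, 0), pmax(Y, 0))
  pairs <- all_pairs_table(data)
  lc <- local_correlation(data, pairs)
  g <- global_correlation(data, pairs)
  expect_lt(max(abs(g - lc$global_index)), 1e-12)
  r <- vapply(seq_len(20), function(j)
    stats::cor(as.numeric(data$rna[, j]), as.numeric(data$atac[, j])),
    numeric(1))
  expect_lt(max(abs(unname(g) - r)), 1e-12)
})

test_that("independent features on a kNN graph give a near-zero global index", {
  sim <- simulate_multiome(sim_config(
    n_cells = 2000, n_genes = 3, n_peaks = 3,
    pairs = list(list(gene = 1L, peak = 1L, rho = 0, label = "null")),
    dropout_rate = 0, seed = 31))
  g <- global_correlation(sim$data,
                          data.frame(gene_id = sim$truth$gene_id,
                                     peak_id = sim$truth$peak_id,
                                     distance_bp = 0L, relation = "overlap"))
  expect_lt(abs(unname(g)), 0.1)
  # x = y: the global index is a mean of squares, hence nonnegative
  dup <- toy_paired(matrix(c(1, 5, 2, 8, 3), ncol = 1),
                    matrix(c(1, 5, 2, 8, 3), ncol = 1))
  expect_gte(unname(global_correlation(dup, all_pairs_table(dup))), 0)
})

test_that("every L value is finite even when outside [-1, 1]", {
  inst <- random_instance(n = 30, p = 6, seed = 10)
  W <- build_weights(inst$data$connectivities)
  lc <- local_correlation(inst$data, inst$pairs, W = W)
  expect_true(all(is.finite(lc$L)))
})
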