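# Pseudotime binning, occupancy, and dynamic-pair selection.

traj_fixture <- function(n = 100, L = NULL, groups = NULL) {
  L <- L %||% matrix(0.5, n, 3)
  lc <- local_fake(L)
  data <- toy_paired(matrix(runif(n * 2) + 1, n, 2),
                     matrix(runif(n * 2) + 1, n, 2),
                     groups = groups %||% rep(c("A", "B"), each = n / 2),
                     pseudotime = seq(0, 1, length.out = n))
  list(lc = lc, data = data)
}

local_fake <- function(L) {
  p <- ncol(L)
  keys <- paste(sprintf("g%02d", seq_len(p)),
                sprintf("chr1:%d-%d", seq_len(p) * 100L, seq_len(p) * 100L + 50L),
                sep = "|")
  colnames(L) <- keys
  rownames(L) <- sprintf("c%03d", seq_len(nrow(L)))
  pairs <- data.frame(gene_id = sprintf("g%02d", seq_len(p)),
                      peak_id = sprintf("chr1:%d-%d", seq_len(p) * 100L,
                                        seq_len(p) * 100L + 50L),
                      distance_bp = 0L, relation = "overlap")
  structure(list(L = L, pairs = pairs,
                 global_index = stats::setNames(colMeans(L), keys),
                 zeroed_dropouts = FALSE, n_dropped = 0L),
            class = "local_corr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("constant L gives constant curves with zero variability", {
  fx <- traj_fixture()
  cv <- trajectory_curves(fx$lc, fx$data, path = c("A", "B"), n_bins = 10)
  expect_true(all(cv$curve == 0.5))
  cv <- detect_dynamic(cv)
  expect_true(all(cv$variability == 0))
  expect_false(any(cv$dynamic_mask))
})

test_that("equal-count binning splits 100 cells into 10 bins of 10", {
  fx <- traj_fixture(n = 100)
  cv <- trajectory_curves(fx$lc, fx$data, path = c("A", "B"), n_bins = 10)
  expect_true(all(cv$bins$n_cells == 10))
  expect_true(all(diff(cv$bins$t_center) > 0))   # ordered by pseudotime
})

test_that("bin means are exact group means and occupancy rows sum to one", {
  set.seed(5)
  n <- 60
  L <- matrix(rnorm(n * 2), n, 2)
  fx <- traj_fixture(n = n, L = L, groups = rep(c("A", "B"), each = 30))
  cv <- trajectory_curves(fx$lc, fx$data, path = c("A", "B"), n_bins = 6)
  # recompute one bin by hand: cells are already in pseudotime order
  expect_equal(cv$curve[1, 1], mean(L[1:10, 1]), tolerance = 1e-15)
  expect_equal(cv$curve[2, 4], mean(L[31:40, 2]), tolerance = 1e-15)
  expect_lt(max(abs(rowSums(cv$occupancy) - 1)), 1e-12)
  # first bins are pure A, last pure B for this layout
  expect_equal(unname(cv$occupancy[1, "A"]), 1)
  expect_equal(unname(cv$occupancy[6, "B"]), 1)
})

test_that("cells off the path or without pseudotime are excluded", {
  n <- 90
  L <- matrix(seq_len(n) / n, n, 1)
  fx <- traj_fixture(n = n, L = L, groups = rep(c("A", "B", "C"), each = 30))
  fx$data$cell_meta$pseudotime[1:5] <- NA
  cv <- trajectory_curves(fx$lc, fx$data, path = c("A", "B"), n_bins = 5)
  expect_equal(sum(cv$bins$n_cells), 55)   # 60 on path minus 5 NA
})

test_that("empty equal-width bins produce an instructive error", {
  n <- 40
  pt <- c(seq(0, 0.1, length.out = 20), seq(0.9, 1, length.out = 20))
  fx <- traj_fixture(n = n)
  fx$data$cell_meta$pseudotime <- pt
  expect_error(
    trajectory_curves(fx$lc, fx$data, path = c("A", "B"), n_bins = 10,
                      binning = "equal_width"),
    "equal_count", class = "screglink_validation_error")
  expect_error(
    trajectory_curves(fx$lc, fx$data, path = c("A", "B"), n_bins = 2),
    "n_bins", class = "screglink_validation_error")
})

test_that("sd-threshold selection is invariant to affine rescaling of curves", {
  set.seed(8)
  n <- 200
  L <- cbind(matrix(rnorm(n * 8, sd = 0.05), n, 8),
             outer(seq(0, 1, length.out = n), c(1, 1.3)))
  fx <- traj_fixture(n = n, L = L)
  cv <- detect_dynamic(trajectory_curves(fx$lc, fx$data, c("A", "B"),
                                         n_bins = 10))
  L2 <- L * 7 + 3
  fx2 <- traj_fixture(n = n, L = L2)
  cv2 <- detect_dynamic(trajectory_curves(fx2$lc, fx2$data, c("A", "B"),
                                          n_bins = 10))
  expect_identical(unname(cv$dynamic_mask), unname(cv2$dynamic_mask))
})

test_that("top_n selection covers the boundary cases", {
  fx <- traj_fixture(n = 60, L = matrix(rnorm(60 * 4), 60, 4))
  cv <- trajectory_curves(fx$lc, fx$data, c("A", "B"), n_bins = 5)
  expect_error(detect_dynamic(cv, "top_n", k = 0), "k",
               class = "screglink_validation_error")
  all_sel <- detect_dynamic(cv, "top_n", k = 4)
  expect_true(all(all_sel$dynamic_mask))
})

test_that("a ramped coupling yields a rising binned curve", {
  sim <- simulate_multiome(sim_config(
    n_cells = 2500, n_genes = 12, n_peaks = 12,
    pairs = c(lapply(1:3, function(j)
      list(gene = j, peak = j, rho = function(t, g) 0.8 * t,
           label = "ramp")),
      lapply(4:12, function(j) list(gene = j, peak = j, rho = 0,
                                    label = "null"))),
    seed = 83))
  pairs <- data.frame(gene_id = sim$data$gene_ids,
                      peak_id = sim$data$peak_ids,
                      distance_bp = 0L, relation = "overlap")
  lc <- local_correlation(sim$data, pairs)
  cv <- trajectory_curves(lc, sim$data, path = paste0("g", 1:4), n_bins = 8)
  rho_sp <- vapply(1:3, function(j)
    stats::cor(seq_len(8), cv$curve[j, ], method = "spearman"), numeric(1))
  expect_gt(stats::median(rho_sp), 0.7)
})

test_that("mean-zero time-varying coupling is caught by variability but missed by Pearson", {
  # coupling swings from -0.85 to +0.85 and time-averages to ~0
  sim <- simulate_multiome(sim_config(
    n_cells = 4000, n_genes = 100, n_peaks = 100,
    pairs = c(lapply(1:20, function(j)
      list(gene = j, peak = j, rho = function(t, g) 0.85 * (2 * t - 1),
           label = "swing")),
      lapply(21:100, function(j) list(gene = j, peak = j, rho = 0,
                                      label = "null"))),
    seed = 29))
  pairs <- data.frame(gene_id = sim$data$gene_ids,
                      peak_id = sim$data$peak_ids,
                      distance_bp = 0L, relation = "overlap")
  lc <- local_correlation(sim$data, pairs)
  cv <- detect_dynamic(
    trajectory_curves(lc, sim$data, path = paste0("g", 1:4), n_bins = 10),
    method = "sd_threshold", k = 1.0)
  swing_keys <- sim$truth$pair_key[sim$truth$label == "swing"]
  recovered <- sum(cv$dynamic_mask[swing_keys])
  expect_gte(recovered, 18)                       # >= 90% of varying pairs
  r <- pearson_baseline(sim$data, pairs)
  n_pearson <- sum(abs(r) >= 0.1, na.rm = TRUE)
  expect_gt(sum(cv$dynamic_mask), n_pearson)
})
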