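# Synthetic paired-multiome generator with known ground-truth gene-peak
# coupling.
#
# Generative model: each cell carries a latent pseudotime t ~ U(0, 1);
# groups are contiguous pseudotime segments (differentiation stages).
# For a designed pair with coupling rho(t, group), the latent gene and peak
# signals of cell i are an exactly rho_i-correlated standard Gaussian pair;
# undesigned features are independent Gaussians. Latent values are shifted
# (+shift), perturbed with independent measurement noise (noise_sd) and
# truncated at zero, emulating library-size-normalized log1p expression /
# accessibility intensities; technical dropout then zeroes a Bernoulli
# fraction of entries per modality. The cell graph is a symmetrized k-NN
# graph on the latent coordinates (t and a group offset) with a sharp
# Gaussian kernel (sigma = mean nearest-neighbor distance), mimicking the
# rapidly decaying connectivities of UMAP-style fuzzy graphs.

#' Simulation configuration
#'
#' @param n_cells number of cells.
#' @param n_genes,n_peaks number of features per modality (must be >= the
#'   number of designed pairs).
#' @param n_groups number of cell groups (contiguous pseudotime segments).
#' @param group_props group proportions (sum to 1); default equal.
#' @param pairs list of pair designs, each a list with \code{gene} and
#'   \code{peak} (indices), \code{rho} (a number in [-0.95, 0.95] or a
#'   function \code{rho(t, group)} returning per-cell couplings), and an
#'   optional \code{label}. Each gene/peak may appear in at most one design.
#' @param dropout_rate probability an entry is zeroed, per modality
#'   (scalar, or length-2 vector c(rna, atac)); default 0.05.
#' @param noise_sd sd of independent measurement noise added on the latent
#'   scale; default 0.2.
#' @param knn_k neighbors for the graph; default 10.
#' @param seed RNG seed driving every stochastic step.
#' @param shift latent shift before truncation at zero; default 2.
#' @param t_scale,group_sep scaling of pseudotime and group one-hot
#'   coordinates in the latent space the graph is built on; defaults 4 and
#'   0.5.
#' @param graph_from \code{"latent"} (default; graph built on the true
#'   latent coordinates, so neighborhood quality is controlled) or
#'   \code{"data"} (realistic mode: graph built from principal components
#'   of the simulated matrices).
#' @return a \code{sim_config} list, validated.
#' @export
sim_config <- function(n_cells = 2000L, n_genes = 100L, n_peaks = 100L,
                       n_groups = 4L, group_props = NULL, pairs = list(),
                       dropout_rate = 0.05, noise_sd = 0.2, knn_k = 10L,
                       seed = 1L, shift = 2, t_scale = 4, group_sep = 0.5,
                       graph_from = c("latent", "data")) {
  graph_from <- match.arg(graph_from)
  group_props <- group_props %||% rep(1 / n_groups, n_groups)
  if (abs(sum(group_props) - 1) > 1e-8) {
    stop_validation("group proportions must sum to 1")
  }
  if (length(group_props) != n_groups) {
    stop_validation("need %d group proportions", n_groups)
  }
  if (length(dropout_rate) == 1L) dropout_rate <- rep(dropout_rate, 2L)
  if (any(dropout_rate < 0) || any(dropout_rate >= 1)) {
    stop_validation("'dropout_rate' must be in [0, 1)")
  }
  gidx <- vapply(pairs, function(p) as.integer(p$gene), 1L)
  pidx <- vapply(pairs, function(p) as.integer(p$peak), 1L)
  if (anyDuplicated(gidx) || anyDuplicated(pidx)) {
    stop_validation("each gene and peak may appear in at most one designed pair")
  }
  if (length(gidx) && (max(gidx) > n_genes || max(pidx) > n_peaks)) {
    stop_validation("designed pair indices exceed feature counts")
  }
  for (p in pairs) {
    if (is.numeric(p$rho) && any(abs(p$rho) > 0.95)) {
      stop_validation("designed |rho| must be <= 0.95")
    }
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_peaks = as.integer(n_peaks), n_groups = as.integer(n_groups),
                 group_props = group_props, pairs = pairs,
                 dropout_rate = dropout_rate, noise_sd = noise_sd,
                 knn_k = as.integer(knn_k), seed = seed, shift = shift,
                 t_scale = t_scale, group_sep = group_sep,
                 graph_from = graph_from),
            class = "sim_config")
}

# symmetrized k-NN connectivity graph with sharp Gaussian kernel weights
knn_connectivities <- function(coord, k) {
  n <- nrow(coord)
  D <- as.matrix(stats::dist(coord))
  k <- min(k, n - 1L)
  ii <- integer(n * k); jj <- integer(n * k); dd <- numeric(n * k)
  d1 <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    ord <- ord[ord != i][seq_len(k)]
    d1[i] <- D[i, ord[1]]
    at <- ((i - 1L) * k + 1L):(i * k)
    ii[at] <- i; jj[at] <- ord; dd[at] <- D[i, ord]
  }
  sigma2 <- mean(d1)^2
  if (sigma2 == 0) sigma2 <- 1e-12
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = exp(-dd^2 / (2 * sigma2)),
                            dims = c(n, n))
  Kt <- Matrix::t(K)
  # elementwise max(K, t(K)), staying sparse
  methods::as((K + Kt + abs(K - Kt)) / 2, "CsparseMatrix")
}

eval_rho <- function(design, t, group) {
  r <- design$rho
  v <- if (is.function(r)) r(t, group) else rep(as.numeric(r), length(t))
  if (length(v) == 1L) v <- rep(v, length(t))
  if (length(v) != length(t) || anyNA(v)) {
    stop_validation("coupling function returned an invalid rho vector")
  }
  if (any(abs(v) > 0.95)) {
    stop_validation("designed |rho| must be <= 0.95 (got %.3f)",
                    max(abs(v)))
  }
  v
}

#' Simulate a paired multiome dataset with known coupling
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{data} (a \code{paired_omics}), \code{truth}
#'   (data.frame: gene_id, peak_id, pair_key, label), \code{latent}
#'   (list with the exact latent Gaussian matrices for designed pairs,
#'   before shift/noise/truncation/dropout -- useful for calibration
#'   checks), and \code{config}.
#' @export
simulate_multiome <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_validation("'config' must come from sim_config()")
  }
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    t <- stats::runif(n)
    qs <- stats::quantile(t, cumsum(c(0, cfg$group_props)))
    group <- cut(t, breaks = qs, include.lowest = TRUE,
                 labels = paste0("g", seq_len(cfg$n_groups)))
    onehot <- stats::model.matrix(~ group - 1)
    latent_coord <- cbind(t * cfg$t_scale, onehot * cfg$group_sep)

    # latent standard-normal features
    Zg <- matrix(stats::rnorm(n * cfg$n_genes), n, cfg$n_genes)
    Zp <- matrix(stats::rnorm(n * cfg$n_peaks), n, cfg$n_peaks)
    lat_gene <- list(); lat_peak <- list()
    for (d in cfg$pairs) {
      rho <- eval_rho(d, t, group)
      zp <- rho * Zg[, d$gene] + sqrt(1 - rho^2) * Zp[, d$peak]
      Zp[, d$peak] <- zp
      lat_gene[[length(lat_gene) + 1L]] <- Zg[, d$gene]
      lat_peak[[length(lat_peak) + 1L]] <- zp
    }

    X <- pmax(Zg + cfg$noise_sd * matrix(stats::rnorm(n * cfg$n_genes), n) +
                cfg$shift, 0)
    Y <- pmax(Zp + cfg$noise_sd * matrix(stats::rnorm(n * cfg$n_peaks), n) +
                cfg$shift, 0)
    if (cfg$dropout_rate[1] > 0) {
      X[matrix(stats::runif(n * cfg$n_genes), n) < cfg$dropout_rate[1]] <- 0
    }
    if (cfg$dropout_rate[2] > 0) {
      Y[matrix(stats::runif(n * cfg$n_peaks), n) < cfg$dropout_rate[2]] <- 0
    }

    gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
    # coordinate-encoded peak ids on a synthetic chromosome
    peak_start <- seq_len(cfg$n_peaks) * 2000L
    peak_ids <- sprintf("chrS:%d-%d", peak_start, peak_start + 500L)
    colnames(X) <- gene_ids
    colnames(Y) <- peak_ids
    cell_ids <- sprintf("cell%05d", seq_len(n))

    coord_for_graph <- if (cfg$graph_from == "latent") latent_coord else {
      pc <- stats::prcomp(cbind(X, Y), rank. = 5L)
      pc$x
    }
    conn <- knn_connectivities(coord_for_graph, cfg$knn_k)

    emb <- cbind(latent_coord[, 1] + stats::rnorm(n, sd = 0.05),
                 as.integer(group) * cfg$group_sep + stats::rnorm(n, sd = 0.05))

    meta <- data.frame(cell_id = cell_ids, group = as.character(group),
                       pseudotime = t, path = "main",
                       stringsAsFactors = FALSE)
    data <- paired_omics(rna = X, atac = Y, cell_meta = meta,
                         connectivities = conn, embedding = emb)

    truth <- if (length(cfg$pairs)) {
      data.frame(
        gene_id = gene_ids[vapply(cfg$pairs, function(p) p$gene, 1L)],
        peak_id = peak_ids[vapply(cfg$pairs, function(p) p$peak, 1L)],
        label = vapply(cfg$pairs,
                       function(p) p$label %||% "designed", ""),
        stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = character(), peak_id = character(),
                 label = character(), stringsAsFactors = FALSE)
    }
    if (nrow(truth)) truth$pair_key <- paste(truth$gene_id, truth$peak_id,
                                             sep = "|")
    list(data = data, truth = truth,
         latent = list(gene = lat_gene, peak = lat_peak),
         config = cfg)
  })
}

# designed pairs: gene j coupled to peak j
design_pairs <- function(n_sig, n_decoy, rho, label) {
  sig <- lapply(seq_len(n_sig), function(j) {
    list(gene = j, peak = j, rho = rho, label = label)
  })
  decoy <- lapply(seq_len(n_decoy), function(j) {
    list(gene = n_sig + j, peak = n_sig + j, rho = 0, label = "null")
  })
  c(sig, decoy)
}

#' Named preset simulation scenarios
#'
#' Presets covering the study conditions exercised by the test-suite and
#' acceptance analyses:
#' \describe{
#'   \item{null}{2000 cells, 1000 uncoupled pairs; marker/FDR calibration.}
#'   \item{cluster_marker}{1200 cells in 4 equal groups; one pair with
#'     rho = 0.8 in group g2 only, plus 20 uncoupled decoys.}
#'   \item{ramp}{6000 cells; 10 pairs with rho(t) = 0.8 t (coupling grows
#'     along the trajectory) plus 90 flat pairs.}
#'   \item{rise_fall}{6000 cells; 10 pairs with rho(t) = 0.8 sin(pi t)
#'     (mid-trajectory peak) plus 90 flat pairs.}
#'   \item{repressive}{2000 cells; 10 pairs with constant rho = -0.6
#'     (accessible chromatin suppressing expression) plus 90 flat pairs.}
#'   \item{mixed_modules}{6000 cells; three temporal coupling templates
#'     (rising 0.8 t, rise-then-fall 0.8 sin(pi t), falling -0.8 t) with
#'     30 pairs each, for SOM module recovery.}
#' }
#'
#' @param seed RNG seed stored in every returned config; default 1.
#' @return named list of \code{sim_config} objects.
#' @export
standard_scenarios <- function(seed = 1L) {
  ramp_fun <- function(t, g) 0.8 * t
  risefall_fun <- function(t, g) 0.8 * sin(pi * t)
  fall_fun <- function(t, g) -0.8 * t
  marker_fun <- function(t, g) ifelse(g == "g2", 0.8, 0)
  list(
    null = sim_config(
      n_cells = 2000L, n_genes = 1000L, n_peaks = 1000L,
      pairs = design_pairs(0L, 1000L, 0, "null"), seed = seed),
    cluster_marker = sim_config(
      n_cells = 1200L, n_genes = 21L, n_peaks = 21L,
      pairs = c(list(list(gene = 1L, peak = 1L, rho = marker_fun,
                          label = "marker_g2")),
                lapply(2:21, function(j) list(gene = j, peak = j, rho = 0,
                                              label = "null"))),
      seed = seed),
    ramp = sim_config(
      n_cells = 6000L, n_genes = 100L, n_peaks = 100L,
      pairs = design_pairs(10L, 90L, ramp_fun, "ramp"), seed = seed),
    rise_fall = sim_config(
      n_cells = 6000L, n_genes = 100L, n_peaks = 100L,
      pairs = design_pairs(10L, 90L, risefall_fun, "rise_fall"), seed = seed),
    repressive = sim_config(
      n_cells = 2000L, n_genes = 100L, n_peaks = 100L,
      pairs = design_pairs(10L, 90L, -0.6, "repressive"), seed = seed),
    mixed_modules = sim_config(
      n_cells = 6000L, n_genes = 90L, n_peaks = 90L,
      pairs = c(
        lapply(1:30, function(j) list(gene = j, peak = j, rho = ramp_fun,
                                      label = "rising")),
        lapply(31:60, function(j) list(gene = j, peak = j,
                                       rho = risefall_fun,
                                       label = "rise_fall")),
        lapply(61:90, function(j) list(gene = j, peak = j, rho = fall_fun,
                                       label = "falling"))),
      seed = seed)
  )
}

#' Write a simulation to an MTX/TSV bundle plus ground truth
#' @param sim result of \code{\link{simulate_multiome}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_paired_omics(sim$data, dir)
  write_tsv(sim$truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
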