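# 1-D self-organizing map over binned regulation curves.
#
# A small online SOM is implemented here directly: the clustering contract
# (1-D unit chain, Gaussian neighborhood, linearly decaying learning rate
# and neighborhood width, explicit seed, deterministic replay) is part of
# the package's reproducibility guarantees, so the trainer is kept
# self-contained and fully specified.

# X: m x d matrix of samples; returns codebooks (units x d) and assignment
som_train_1d <- function(X, m_units, epochs, learning_rate, sigma, seed) {
  m <- nrow(X)
  if (m < m_units) {
    stop_validation("fewer samples (%d) than SOM units (%d)", m, m_units)
  }
  with_seed(seed, {
    # init: codebooks from randomly chosen distinct samples
    code <- X[sample.int(m, m_units), , drop = FALSE]
    units <- seq_len(m_units)
    for (s in seq_len(epochs)) {
      frac <- (s - 1) / epochs
      lr <- learning_rate * (1 - frac)
      sg <- max(sigma * (1 - frac), 0.01)
      i <- sample.int(m, 1L)
      x <- X[i, ]
      d2 <- rowSums(sweep(code, 2, x, "-")^2)
      bmu <- which.min(d2)
      theta <- exp(-((units - bmu)^2) / (2 * sg^2))
      code <- code + lr * theta * sweep(-code, 2, x, "+")
    }
    assign_bmu <- function(x) {
      which.min(rowSums(sweep(code, 2, x, "-")^2))
    }
    list(codebooks = code,
         assignment = apply(X, 1, assign_bmu))
  })
}

#' Cluster dynamic regulation curves into temporal modules with a SOM
#'
#' Each dynamic pair's binned curve is z-normalized across bins (so modules
#' group temporal shapes, not magnitudes) and a 1-D self-organizing map of
#' \code{m_units} units is trained on the normalized curves. Every dynamic
#' pair is assigned the module of its best-matching unit; the trained unit
#' codebooks are the module prototype curves.
#'
#' @param curves a \code{trajectory_curves} object with
#'   \code{dynamic_mask} filled (see \code{\link{detect_dynamic}}).
#' @param m_units number of modules (SOM units on a 1-D chain); default 3.
#' @param epochs training iterations (one randomly drawn curve each);
#'   default 2000.
#' @param learning_rate initial learning rate, decaying linearly to 0;
#'   default 0.5.
#' @param sigma initial Gaussian neighborhood width in unit-index distance,
#'   decaying linearly (floored at 0.01); default \code{m_units / 2}.
#' @param seed mandatory RNG seed; the same seed and inputs reproduce the
#'   assignment exactly.
#' @return an object of class \code{som_modules}: list with
#'   \code{module_id} (named integer, 1..m_units, per dynamic pair),
#'   \code{prototypes} (m_units x bins codebook matrix, normalized curve
#'   scale), \code{som_config}, and \code{excluded} (zero-sd curves, if
#'   any).
#' @export
dynamic_modules <- function(curves, m_units = 3L, epochs = 2000L,
                            learning_rate = 0.5, sigma = m_units / 2,
                            seed) {
  if (missing(seed)) stop_validation("'seed' is required for SOM training")
  if (!inherits(curves, "trajectory_curves") || is.null(curves$dynamic_mask)) {
    stop_validation("run detect_dynamic() before dynamic_modules()")
  }
  dyn <- which(curves$dynamic_mask)
  if (length(dyn) < m_units) {
    stop_validation(
      "only %d dynamic pair(s) but m_units = %d; reduce m_units",
      length(dyn), m_units)
  }
  M <- curves$curve[dyn, , drop = FALSE]
  sds <- apply(M, 1, stats::sd)
  excluded <- rownames(M)[sds == 0]
  if (length(excluded)) {
    warning(sprintf("%d zero-sd curve(s) excluded from SOM training",
                    length(excluded)))
    M <- M[sds > 0, , drop = FALSE]
    if (nrow(M) < m_units) {
      stop_validation("fewer usable curves than SOM units after exclusion")
    }
  }
  Z <- t(apply(M, 1, function(v) (v - mean(v)) / stats::sd(v)))
  fit <- som_train_1d(Z, m_units = m_units, epochs = epochs,
                      learning_rate = learning_rate, sigma = sigma,
                      seed = seed)
  structure(list(
    module_id = stats::setNames(as.integer(fit$assignment), rownames(Z)),
    prototypes = fit$codebooks,
    som_config = list(grid = c(m_units, 1L), epochs = epochs,
                      learning_rate = learning_rate, sigma = sigma,
                      seed = seed),
    excluded = excluded), class = "som_modules")
}

#' @export
print.som_modules <- function(x, ...) {
  tab <- table(x$module_id)
  cat(sprintf("som_modules: %d curves in %d module(s) [%s]\n",
              length(x$module_id), nrow(x$prototypes),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  seed %s, %d epochs\n", format(x$som_config$seed),
              x$som_config$epochs))
  invisible(x)
}

#' Write SOM module assignments (TSV) and configuration (JSON)
#' @param modules a \code{som_modules} object.
#' @param prefix output path prefix; writes \code{<prefix>_modules.tsv} and
#'   \code{<prefix>_som_config.json}.
#' @return invisibly, the paths written.
#' @export
write_som_modules <- function(modules, prefix) {
  p1 <- paste0(prefix, "_modules.tsv")
  write_tsv(data.frame(pair_key = names(modules$module_id),
                       module_id = unname(modules$module_id)), p1)
  p2 <- paste0(prefix, "_som_config.json")
  jsonlite::write_json(modules$som_config, p2, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(p1, p2))
}
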