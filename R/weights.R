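# Row-stochastic spatial weight matrix built from a cell-cell connectivity
# graph.

#' Build the row-standardized weight matrix W
#'
#' Takes a nonnegative cell-cell connectivity matrix (e.g. WNN graph
#' connectivities), sets the diagonal to \code{self_weight} so every cell is
#' its own neighbor, and row-standardizes, so each row of W sums to 1. A
#' cell with no neighbors degenerates to a pure self-row (its spatial lag is
#' its own value).
#'
#' @param connectivities n x n nonnegative (sparse) connectivity matrix.
#' @param self_weight positive diagonal value inserted before
#'   standardization; default 1.0. Exposed because connectivity scales vary
#'   between graph constructions.
#' @return a \code{dgCMatrix} with unit row sums and strictly positive
#'   diagonal.
#' @export
build_weights <- function(connectivities, self_weight = 1.0) {
  if (!is.numeric(self_weight) || self_weight <= 0) {
    stop_validation("'self_weight' must be > 0")
  }
  W <- methods::as(as_sparse(connectivities), "CsparseMatrix")
  if (nrow(W) != ncol(W)) stop_validation("connectivities must be square")
  if (nrow(W) < 2L) stop_validation("need at least 2 cells")
  if (length(W@x) && min(W@x) < 0) {
    stop_validation("connectivities contains negative entries")
  }
  diag(W) <- self_weight
  W <- Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
  methods::as(W, "CsparseMatrix")
}

# TRUE iff W is row-stochastic with positive diagonal (tol on row sums)
check_weight_matrix <- function(W, tol = 1e-12) {
  if (nrow(W) != ncol(W)) {
    stop_validation("weight matrix must be square")
  }
  if (max(abs(Matrix::rowSums(W) - 1)) > tol) {
    stop_validation(
      "weight matrix rows must sum to 1 (max deviation %.2e); use build_weights()",
      max(abs(Matrix::rowSums(W) - 1)))
  }
  if (min(Matrix::diag(W)) <= 0) {
    stop_validation("weight matrix must have a strictly positive diagonal")
  }
  invisible(TRUE)
}

#' Spatial lag of a vector over the cell graph
#'
#' The lag of cell i is the weighted average of the values of its graph
#' neighbors (itself included): \code{lag_i = sum_j W[i, j] * v[j]}.
#'
#' @param W row-standardized weight matrix from \code{\link{build_weights}}.
#' @param v numeric vector of length \code{nrow(W)}.
#' @return numeric vector of lagged values.
#' @export
spatial_lag <- function(W, v) {
  if (length(v) != ncol(W)) {
    stop_validation("length(v) = %d does not match ncol(W) = %d",
                    length(v), ncol(W))
  }
  as.numeric(W %*% v)
}
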