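#' Validate a precomputed dissimilarity matrix
#'
#' Checks that `x` is a square, symmetric, zero-diagonal, non-negative
#' dissimilarity matrix and returns it in the canonical form used by every
#' silhouette computation in the package. Tiny numerical asymmetries (at most
#' `tol`) are repaired by averaging `x` with its transpose; anything larger is
#' an error, as are negative entries, a non-zero diagonal, and matrices with
#' fewer than two rows.
#'
#' @param x A square numeric matrix of pairwise dissimilarities, or an object
#'   coercible to one (e.g. a [stats::dist] object).
#' @param tol Tolerance for the symmetry and zero-diagonal checks. Default
#'   `1e-9`.
#' @return A numeric matrix of class `"dist_matrix"` with row and column names
#'   (generated as `"S1"`, `"S2"`, ... when absent).
#' @seealso [euclidean_distances()] to build one from a data matrix.
#' @examples
#' as_dist_matrix(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
as_dist_matrix <- function(x, tol = 1e-9) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (inherits(x, "dist_matrix")) return(x)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("dissimilarities must be numeric")
  n <- nrow(x)
  if (n != ncol(x)) stop("dissimilarity matrix must be square")
  if (n < 2L) stop("need at least two samples")
  if (any(!is.finite(x))) stop("non-finite dissimilarity")
  asym <- max(abs(x - t(x)))
  if (asym > tol) {
    stop(sprintf("matrix is asymmetric beyond tolerance (max |d_ij - d_ji| = %g)", asym))
  }
  x <- (x + t(x)) / 2
  if (max(abs(diag(x))) > tol) stop("diagonal of a dissimilarity matrix must be zero")
  diag(x) <- 0
  if (any(x < 0)) stop("negative dissimilarity")
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  dimnames(x) <- list(ids, ids)
  class(x) <- c("dist_matrix", class(x))
  x
}

#' Euclidean distance matrix from a data matrix
#'
#' Computes all pairwise Euclidean distances between the rows of a
#' samples-by-features matrix. This is the metric used throughout the
#' refinement and benchmark code.
#'
#' @param data Numeric matrix (or data frame) with one row per sample and one
#'   column per feature; all entries must be finite.
#' @return A `"dist_matrix"` (see [as_dist_matrix()]) with `nrow(data)` rows.
#' @examples
#' euclidean_distances(cbind(c(0, 3), c(0, 4)))["S1", "S2"] # 5
#' @export
euclidean_distances <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data matrix must be numeric")
  if (nrow(data) < 2L) stop("need at least two samples")
  if (any(!is.finite(data))) stop("non-finite entries in data matrix")
  d <- as.matrix(stats::dist(data, method = "euclidean"))
  if (!is.null(rownames(data))) dimnames(d) <- list(rownames(data), rownames(data))
  as_dist_matrix(d)
}

# Map an arbitrary label vector (character, factor, integer) onto dense
# integer codes 1..k, remembering the original values for reporting.
.encode_labels <- function(labels, n = NULL) {
  if (is.list(labels) && !is.null(labels$idx)) return(labels)
  labels <- if (is.factor(labels)) as.character(labels) else labels
  if (!is.null(n) && length(labels) != n) {
    stop(sprintf("labeling has length %d but the distance matrix has %d samples",
                 length(labels), n))
  }
  if (anyNA(labels)) stop("labels must not contain NA")
  lev <- sort(unique(labels))
  list(idx = match(labels, lev), levels = lev, k = length(lev))
}

.decode_labels <- function(idx, levels) levels[idx]
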