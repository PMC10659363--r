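#' Contingency table of two labelings
#'
#' Cross-tabulates a predicted against a reference (true) labeling: entry
#' `(i, j)` counts the samples placed in predicted cluster `i` and true
#' cluster `j`.
#'
#' @param pred,truth Label vectors of equal length.
#' @return An integer matrix with predicted clusters as rows and true
#'   clusters as columns, with `row_sums`, `col_sums` and `n` attributes.
#' @export
contingency <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("labelings differ in length")
  tab <- table(pred = as.character(pred), truth = as.character(truth))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  structure(m, row_sums = rowSums(m), col_sums = colSums(m), n = sum(m))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (Hubert-Arabie form),
#' computed from exact integer pair counts over the contingency table.
#' Equals 1 exactly when the partitions are identical up to label
#' permutation, and is symmetric in its arguments. In the degenerate case
#' where the adjustment denominator vanishes (e.g. both partitions a single
#' cluster) the index is 1 when the partitions agree exactly and 0
#' otherwise.
#'
#' @param pred,truth Label vectors of equal length `n >= 2`.
#' @return A single number, at most 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 1, 2), c(1, 1, 2, 2)) # 0
#' adjusted_rand_index(c("a", "b", "b"), c(2, 1, 1)) # 1
#' @export
adjusted_rand_index <- function(pred, truth) {
  tab <- contingency(pred, truth)
  n <- attr(tab, "n")
  if (n < 2L) stop("need at least two samples")
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(attr(tab, "row_sums"), 2))
  sum_b <- sum(choose(attr(tab, "col_sums"), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxim <- (sum_a + sum_b) / 2
  if (maxim == expected) {
    return(if (is_perfect(pred, truth)) 1 else 0)
  }
  (sum_ij - expected) / (maxim - expected)
}

#' Normalized clustering entropy
#'
#' External impurity measure: for each predicted cluster the entropy of its
#' composition across the true clusters, normalized by `log K` (`K` = number
#' of true clusters) so a maximally mixed cluster scores 1, then averaged
#' over predicted clusters weighted by cluster size. Zero iff every
#' predicted cluster is pure, i.e. drawn from a single true cluster.
#'
#' @param pred,truth Label vectors of equal length; `truth` must contain at
#'   least two distinct labels (otherwise the normalizer `log K` vanishes).
#' @return A number in `[0, 1]`.
#' @examples
#' clustering_entropy(c(1, 1, 1, 2), c(1, 1, 2, 2)) # about 0.6887
#' @export
clustering_entropy <- function(pred, truth) {
  tab <- contingency(pred, truth)
  K <- ncol(tab)
  if (K < 2L) stop("entropy normalizer undefined: fewer than two true clusters")
  sizes <- attr(tab, "row_sums")
  n <- attr(tab, "n")
  p <- tab / sizes                       # row-wise composition
  plogp <- ifelse(p > 0, p * log(p), 0)  # 0 log 0 := 0
  e_cluster <- -rowSums(plogp) / log(K)
  sum(sizes / n * e_cluster)
}

#' Within-group sum of squares
#'
#' Sum over clusters of squared Euclidean deviations of each sample from its
#' cluster centroid — the k-means objective evaluated at an arbitrary
#' labeling.
#'
#' @param data Numeric samples-by-features matrix (or data frame).
#' @param labels Label vector with one entry per row of `data`.
#' @return A non-negative number.
#' @examples
#' wss(matrix(c(0, 1, 10, 11), ncol = 1), c(1, 1, 2, 2)) # 1
#' @export
wss <- function(data, labels) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) == 0L) stop("data must be a non-empty numeric matrix")
  if (nrow(data) != length(labels)) stop("labels length must match rows of data")
  idx <- .encode_labels(labels)$idx
  centroids <- rowsum(data, idx) / tabulate(idx)
  sum((data - centroids[idx, , drop = FALSE])^2)
}

#' Normalized within-group sum of squares
#'
#' [wss()] of the predicted labeling divided by [wss()] of the true
#' labeling, removing the dependence on dataset size. Values below 1 are
#' possible: a labeling can achieve a lower sum of squares than the
#' generative truth.
#'
#' @param data Numeric samples-by-features matrix.
#' @param pred,truth Label vectors; `wss(data, truth)` must be positive.
#' @return A positive number; exactly 1 when `pred` equals `truth`.
#' @export
normalized_wss <- function(data, pred, truth) {
  denom <- wss(data, truth)
  if (denom <= 0) stop("true labeling has zero within-group sum of squares")
  wss(data, pred) / denom
}

#' Is a clustering a perfect recovery of the truth?
#'
#' `TRUE` iff the two labelings induce the same partition, i.e. are
#' identical up to a permutation of label names. The count of perfect
#' recoveries over a study is the Perfect Classification Count (PCC).
#'
#' @param pred,truth Label vectors of equal length.
#' @return A logical scalar.
#' @export
is_perfect <- function(pred, truth) {
  tab <- contingency(pred, truth)
  all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
}

#' All validity indices for one clustering solution
#'
#' Convenience wrapper computing the five indices used in method
#' comparisons: average silhouette width, adjusted Rand index, normalized
#' within-group sum of squares, normalized entropy, and the perfect-recovery
#' flag.
#'
#' @param data Samples-by-features matrix (for WSS and, when `d` is
#'   missing, Euclidean distances).
#' @param pred,truth Label vectors.
#' @param d Optional precomputed dissimilarity matrix; computed from `data`
#'   when absent.
#' @return A one-row data frame with columns `asw`, `ari`, `nwss`,
#'   `entropy`, `perfect`, `k_found`.
#' @export
evaluate_clustering <- function(data, pred, truth, d = NULL) {
  if (is.null(d)) d <- euclidean_distances(data)
  data.frame(
    asw = mean_silhouette(d, pred),
    ari = adjusted_rand_index(pred, truth),
    nwss = normalized_wss(data, pred, truth),
    entropy = clustering_entropy(pred, truth),
    perfect = is_perfect(pred, truth),
    k_found = length(unique(pred))
  )
}
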