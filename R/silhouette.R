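#' Per-point silhouette profile
#'
#' For every sample `i` with cluster label `C(i)`, computes the cohesion
#' `a_i` (mean dissimilarity to the other members of `C(i)`), the separation
#' `b_i` (minimum over other clusters of the mean dissimilarity to that
#' cluster's members), the silhouette width
#' `s_i = (b_i - a_i) / max(a_i, b_i)`, and the identity of the neighbouring
#' cluster that attains `b_i`. The average silhouette width (ASW) is the
#' arithmetic mean of `s_i` over all samples.
#'
#' Samples that are alone in their cluster get `s_i = 0` by convention
#' (Rousseeuw's choice, matching `cluster::silhouette`); their cohesion is
#' stored as 0 and flagged in the `singleton` column. When two clusters tie
#' for the separation minimum the one with the smallest identifier is
#' reported, so repeated runs are deterministic.
#'
#' @param d A dissimilarity matrix accepted by [as_dist_matrix()].
#' @param labels Cluster assignment vector, one entry per sample. Labels are
#'   opaque identifiers; at least two distinct values must be present.
#' @return An object of class `"silhouette_profile"`: a data frame with
#'   columns `cluster`, `neighbor`, `a`, `b`, `s`, `singleton`, plus
#'   attributes `asw` (mean silhouette width) and `k` (number of clusters).
#' @examples
#' d <- euclidean_distances(matrix(c(0, 1, 10, 11), ncol = 1))
#' prof <- silhouette_profile(d, c(1, 1, 2, 2))
#' attr(prof, "asw") # about 0.8997
#' @export
silhouette_profile <- function(d, labels) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  enc <- .encode_labels(labels, n)
  if (enc$k < 2L) stop("silhouette undefined for a single cluster")
  core <- .sil_core(unclass(d), enc$idx, enc$k)
  out <- data.frame(
    cluster = .decode_labels(enc$idx, enc$levels),
    neighbor = .decode_labels(core$neighbor, enc$levels),
    a = core$a, b = core$b, s = core$s,
    singleton = core$singleton,
    row.names = rownames(d),
    stringsAsFactors = FALSE
  )
  structure(out, asw = mean(core$s), k = enc$k,
            class = c("silhouette_profile", "data.frame"))
}

#' Average silhouette width of a labeling
#'
#' Convenience wrapper returning only the ASW of [silhouette_profile()].
#'
#' @inheritParams silhouette_profile
#' @return A single number in `[-1, 1]`.
#' @export
mean_silhouette <- function(d, labels) {
  attr(silhouette_profile(d, labels), "asw")
}

# Engine shared with the refinement loop: no validation, dense integer codes.
# Cost is one rowsum() over the n x n matrix per call.
.sil_core <- function(D, idx, k) {
  n <- length(idx)
  sizes <- tabulate(idx, nbins = k)
  stopifnot(all(sizes > 0L))                   # codes must be dense 1..k
  sums <- rowsum(D, idx)                       # k x n, rows in code order
  means <- sums / sizes                        # mean dist cluster -> point
  a <- sums[cbind(idx, seq_len(n))] / pmax(sizes[idx] - 1L, 1L)
  singleton <- sizes[idx] == 1L
  a[singleton] <- 0
  tm <- t(means)
  tm[cbind(seq_len(n), idx)] <- Inf            # mask own cluster
  neighbor <- max.col(-tm, ties.method = "first")
  b <- tm[cbind(seq_len(n), neighbor)]
  denom <- pmax(a, b)
  s <- ifelse(denom > 0, (b - a) / denom, 0)
  s[singleton] <- 0
  list(a = a, b = b, s = as.numeric(s), neighbor = neighbor,
       singleton = singleton, sizes = sizes)
}

#' @export
print.silhouette_profile <- function(x, ...) {
  cat(sprintf("Silhouette profile: %d samples, %d clusters, ASW = %.4f\n",
              nrow(x), attr(x, "k"), attr(x, "asw")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... (%d more rows)\n", nrow(x) - 10L))
  invisible(x)
}
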