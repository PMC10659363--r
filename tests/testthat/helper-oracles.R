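# Independent oracles used to cross-check the implementation. These are
# deliberately naive (triple loops, explicit pair counting) and share no code
# with the package internals.

# Naive silhouette: for each point, average distance to every cluster by
# explicit loops, then s = (b - a) / max(a, b); singletons get 0.
oracle_silhouette <- function(D, labels) {
  n <- nrow(D)
  cl <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0L) { s[i] <- 0; next }
    a <- mean(D[i, mates])
    b <- Inf
    for (c in setdiff(cl, own)) {
      b <- min(b, mean(D[i, labels == c]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# Pair-counting adjusted Rand index: classify every unordered pair of points
# as together/apart in each partition, then apply the Hubert-Arabie
# adjustment to the raw agreement counts.
oracle_ari <- function(pred, truth) {
  n <- length(pred)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_p <- pred[i] == pred[j]
      same_t <- truth[i] == truth[j]
      if (same_p && same_t) n11 <- n11 + 1
      else if (!same_p && !same_t) n00 <- n00 + 1
      else if (same_p) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  maxim <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxim == expected) return(as.numeric(n10 + n01 == 0))
  (n11 - expected) / (maxim - expected)
}

# The four-point line 0, 1, 10, 11: two tight pairs, the standard worked
# example for silhouette arithmetic.
line4 <- function() {
  euclidean_distances(matrix(c(0, 1, 10, 11), ncol = 1,
                             dimnames = list(paste0("p", 1:4), "x")))
}

# All labelings of n points into at most k non-empty blocks (up to label
# names), for exhaustive small-instance properties.
all_labelings <- function(n, k) {
  grids <- do.call(expand.grid, rep(list(seq_len(k)), n))
  out <- list()
  seen <- character()
  for (r in seq_len(nrow(grids))) {
    lab <- as.integer(grids[r, ])
    canon <- paste(match(lab, unique(lab)), collapse = ",")
    if (!canon %in% seen) {
      seen <- c(seen, canon)
      out[[length(out) + 1L]] <- as.integer(match(lab, unique(lab)))
    }
  }
  out
}
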