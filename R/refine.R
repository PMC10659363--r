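#' Control parameters for the refinement loop
#'
#' @param max_iterations Maximum number of single-point reassignments before
#'   the loop gives up. Default 1000.
#' @param cycle_window Number of recent silhouette vectors kept to detect
#'   oscillation: if the current vector matches any of the last
#'   `cycle_window` vectors the loop stops. Default 10.
#' @param rounding_digits Decimal places used when comparing silhouette
#'   vectors for cycle detection, guarding against floating-point jitter.
#'   Default 12.
#' @return A list of class `"refine_control"`.
#' @export
refine_control <- function(max_iterations = 1000L, cycle_window = 10L,
                           rounding_digits = 12L) {
  stopifnot(max_iterations >= 1, cycle_window >= 1, rounding_digits >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 cycle_window = as.integer(cycle_window),
                 rounding_digits = as.integer(rounding_digits)),
            class = "refine_control")
}

#' Refine a clustering by silhouette-width optimization
#'
#' The single-start SillyPutty loop. Starting from `labels`, repeatedly:
#' compute the silhouette profile; if every silhouette width is non-negative,
#' stop (`converged`); otherwise move the sample with the most negative width
#' (ties broken by lowest sample index) into its neighbouring cluster — the
#' cluster attaining its separation value `b` — and repeat. The loop also
#' stops when `max_iterations` reassignments have been made, when the same
#' silhouette vector reappears within the last `cycle_window` iterations
#' (`cycle_detected`), or when a move would leave a single cluster
#' (`degenerate`). A cluster emptied by a move is silently dropped, so the
#' effective number of clusters can decrease.
#'
#' @param d A dissimilarity matrix accepted by [as_dist_matrix()].
#' @param labels Initial cluster assignment with at least two distinct
#'   labels, e.g. from [random_labeling()] or any external clusterer.
#' @param control A [refine_control()] list.
#' @return An object of class `"silly_putty"`; see [silly_putty()] for its
#'   components. `termination` is one of `"converged"`, `"max_iterations"`,
#'   `"cycle_detected"`, `"degenerate"`.
#' @examples
#' d <- euclidean_distances(matrix(c(0, 1, 10, 11), ncol = 1))
#' fit <- refine(d, c(1, 1, 1, 2))
#' labels(fit)           # the two-pair partition
#' fit$iterations        # 1
#' @export
refine <- function(d, labels, control = refine_control()) {
  d <- as_dist_matrix(d)
  D <- unclass(d)
  n <- nrow(D)
  enc <- .encode_labels(labels, n)
  if (enc$k < 2L) stop("refinement needs at least two clusters to start")
  idx <- enc$idx
  lev <- enc$levels
  k <- enc$k

  it <- 0L
  hist <- vector("list", control$cycle_window)
  hpos <- 0L
  trace <- list()
  core <- NULL
  termination <- NULL

  repeat {
    core <- .sil_core(D, idx, k)
    if (min(core$s) >= 0) { termination <- "converged"; break }
    key <- round(core$s, control$rounding_digits)
    seen <- FALSE
    for (h in hist) if (!is.null(h) && length(h) == length(key) && all(h == key)) { seen <- TRUE; break }
    if (seen) { termination <- "cycle_detected"; break }
    if (it >= control$max_iterations) { termination <- "max_iterations"; break }
    hpos <- hpos %% control$cycle_window + 1L
    hist[[hpos]] <- key

    worst <- which.min(core$s)            # ties -> lowest sample index
    target <- core$neighbor[worst]
    donor <- idx[worst]
    trace[[length(trace) + 1L]] <- data.frame(
      iteration = it + 1L,
      sample = rownames(D)[worst],
      from = lev[donor], to = lev[target],
      asw = mean(core$s), stringsAsFactors = FALSE)
    idx[worst] <- target
    it <- it + 1L
    if (!any(idx == donor)) {             # donor cluster emptied: drop it
      idx <- ifelse(idx > donor, idx - 1L, idx)
      lev <- lev[-donor]
      k <- k - 1L
      if (k < 2L) { termination <- "degenerate"; core <- NULL; break }
    }
  }

  final_labels <- .decode_labels(idx, lev)
  names(final_labels) <- rownames(D)
  profile <- if (is.null(core)) NULL else {
    structure(data.frame(cluster = .decode_labels(idx, lev),
                         neighbor = .decode_labels(core$neighbor, lev),
                         a = core$a, b = core$b, s = core$s,
                         singleton = core$singleton,
                         row.names = rownames(D), stringsAsFactors = FALSE),
              asw = mean(core$s), k = k,
              class = c("silhouette_profile", "data.frame"))
  }
  structure(list(
    labels = final_labels,
    profile = profile,
    asw = if (is.null(profile)) NA_real_ else attr(profile, "asw"),
    k_effective = k,
    iterations = it,
    termination = termination,
    trace = if (length(trace)) do.call(rbind, trace) else NULL,
    control = control,
    method = "refine",
    n = n
  ), class = "silly_putty")
}

#' Random cluster assignment
#'
#' Assigns each of `n` samples uniformly at random to one of `k` clusters,
#' resampling until every cluster is non-empty. Uses the current RNG state,
#' so wrap in [set.seed()] (or pass `seed` to [silly_putty()]) for
#' reproducibility.
#'
#' @param n Number of samples (`n >= k`).
#' @param k Number of clusters (`2 <= k <= n`).
#' @return An integer vector of length `n` containing all of `1:k`.
#' @export
random_labeling <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k must not exceed n")
  repeat {
    idx <- sample.int(k, n, replace = TRUE)
    if (length(unique(idx)) == k) return(idx)
  }
}

#' Multi-start SillyPutty clustering
#'
#' The standalone clusterer: runs [refine()] from `restarts` independent
#' random assignments of `k` clusters and keeps the run with the largest
#' final average silhouette width (ties go to the earliest restart). Each
#' restart draws its own seed from the master `seed`, so results are
#' reproducible and independent of execution order.
#'
#' @param d A dissimilarity matrix accepted by [as_dist_matrix()], or a
#'   samples-by-features data matrix when `distance = "euclidean"`.
#' @param k Number of clusters to seek (`2 <= k <= n`).
#' @param restarts Number of random starts. Default 100.
#' @param seed Optional master seed (integer) for reproducibility.
#' @param control A [refine_control()] list passed to every restart.
#' @param distance Either `"precomputed"` (default; `d` is already a
#'   dissimilarity matrix) or `"euclidean"` (`d` is a data matrix and
#'   distances are computed once up front).
#' @return An object of class `"silly_putty"` with components `labels`
#'   (named vector of final cluster assignments), `profile` (final
#'   [silhouette_profile()]), `asw`, `k_effective`, `iterations`,
#'   `termination`, `trace`, and for multi-start fits `best_restart`,
#'   `restart_asw` (final ASW of every restart) and `seed`.
#' @examples
#' d <- euclidean_distances(matrix(c(0, 1, 10, 11), ncol = 1))
#' fit <- silly_putty(d, k = 2, restarts = 5, seed = 1)
#' labels(fit)
#' summary(fit)
#' @export
silly_putty <- function(d, k, restarts = 100L, seed = NULL,
                        control = refine_control(),
                        distance = c("precomputed", "euclidean")) {
  distance <- match.arg(distance)
  d <- if (distance == "euclidean") euclidean_distances(d) else as_dist_matrix(d)
  n <- nrow(d)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= n")
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("restarts must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max, restarts)

  best <- NULL
  best_asw <- -Inf
  best_restart <- NA_integer_
  restart_asw <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(restart_seeds[r])
    start <- random_labeling(n, k)
    fit <- refine(d, start, control = control)
    restart_asw[r] <- if (is.na(fit$asw)) -Inf else fit$asw
    if (restart_asw[r] > best_asw) {
      best <- fit
      best_asw <- restart_asw[r]
      best_restart <- r
    }
  }
  best$method <- "silly_putty"
  best$restarts <- restarts
  best$best_restart <- best_restart
  best$restart_asw <- restart_asw
  best$seed <- seed
  best$call <- match.call()
  best
}
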