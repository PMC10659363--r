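#' The factorial simulation design
#'
#' The 27-row design over which methods are compared: every combination of
#' cluster count (12, 3 or 6), low or medium additive noise, sample size
#' (1000 or 600) and feature count (10000 or 5000), plus one high-noise
#' configuration per cluster count at the largest size (1000 samples, 10000
#' features). With the default 19 replicates per row the full study comprises
#' 513 simulated datasets.
#'
#' @return A data frame with columns `dataset` (1..27), `clusters`, `noise`
#'   (`"low"`, `"medium"` or `"high"`), `samples`, `features`.
#' @examples
#' nrow(design_grid()) # 27
#' @export
design_grid <- function() {
  block <- function(k) {
    data.frame(
      clusters = k,
      noise = c("high", "low", "low", "low", "low",
                "medium", "medium", "medium", "medium"),
      samples = c(1000L, 1000L, 1000L, 600L, 600L, 1000L, 1000L, 600L, 600L),
      features = c(10000L, 10000L, 5000L, 10000L, 5000L,
                   10000L, 5000L, 10000L, 5000L),
      stringsAsFactors = FALSE
    )
  }
  grid <- rbind(block(12L), block(3L), block(6L))
  cbind(dataset = seq_len(nrow(grid)), grid)
}

#' Additive noise model for simulated expression data
#'
#' Observed log-scale expression is signal plus Gaussian noise,
#' `Y = S + eps` with `eps ~ N(nu, tau_g)`: the noise mean `nu` is a small
#' global shift (default 0.1) and the per-feature standard deviation `tau_g`
#' is drawn from a gamma distribution whose mean sets the noise level. The
#' named levels use gamma means 0.3 (`low`), 0.9 (`medium`) and 1.8
#' (`high`) with shape 4; these calibrations are package choices (see the
#' methods vignette) that order the levels by clustering difficulty.
#'
#' @param level `"low"`, `"medium"` or `"high"`; ignored when `tau_mean` is
#'   given explicitly.
#' @param nu Mean of the additive noise, log-scale units. Default 0.1.
#' @param tau_shape Gamma shape for the per-feature noise sd. Default 4.
#' @param tau_mean Gamma mean for the per-feature noise sd; overrides
#'   `level`. `0` gives noiseless data shifted by `nu`.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(level = c("low", "medium", "high"), nu = 0.1,
                        tau_shape = 4, tau_mean = NULL) {
  if (is.null(tau_mean)) {
    level <- match.arg(level)
    tau_mean <- c(low = 0.3, medium = 0.9, high = 1.8)[[level]]
  } else {
    level <- "custom"
    if (tau_mean < 0) stop("tau_mean must be non-negative")
  }
  if (!is.finite(nu)) stop("nu must be finite")
  if (tau_shape <= 0) stop("tau_shape must be positive")
  structure(list(level = level, nu = nu, tau_shape = tau_shape,
                 tau_mean = tau_mean), class = "noise_model")
}

#' Simulate a log-scale expression dataset with known clusters
#'
#' Generates a gene-expression-like samples-by-features matrix on the log2
#' scale with a known cluster structure, emulating cancer-transcriptomics
#' simulators. Cluster sizes are multinomial with equal probabilities,
#' resampled until the smallest cluster has at least `min_cluster_size`
#' members. A fraction `informative_frac` of features carries signal: each
#' informative feature gets an independent cluster-specific shift drawn from
#' `N(0, shift_sd^2)` added to a global per-feature baseline
#' `N(baseline_mean, baseline_sd^2)`; the remaining features are baseline
#' only. Observed values add noise per [noise_model()]: per-feature sd
#' `tau_g ~ Gamma`, entries `eps ~ N(nu, tau_g)`.
#'
#' @param clusters Number of clusters (>= 2).
#' @param samples Number of samples.
#' @param features Number of features.
#' @param noise A [noise_model()], or a level name passed to it.
#' @param seed Optional seed; a fixed seed reproduces the dataset bitwise.
#' @param informative_frac Fraction of features carrying cluster signal.
#'   Default 0.1.
#' @param shift_sd Standard deviation of cluster-specific shifts on the log2
#'   scale. Default 1.0.
#' @param baseline_mean,baseline_sd Global per-feature baseline expression
#'   distribution. Defaults 6 and 1.5 (log2 scale).
#' @param min_cluster_size Smallest admissible cluster (default 5, reduced
#'   automatically when `samples %/% clusters` is smaller).
#' @return An object of class `"sim_dataset"`: list with `Y` (observed,
#'   samples x features), `S` (noise-free signal), `truth` (integer labels),
#'   `tau` (per-feature noise sd), `noise`, and `config`.
#' @examples
#' sim <- simulate_dataset(3, 60, 50, noise = "low", seed = 1)
#' table(sim$truth)
#' @export
simulate_dataset <- function(clusters, samples, features,
                             noise = noise_model("low"), seed = NULL,
                             informative_frac = 0.1, shift_sd = 1.0,
                             baseline_mean = 6, baseline_sd = 1.5,
                             min_cluster_size = 5L) {
  if (is.character(noise)) noise <- noise_model(noise)
  stopifnot(inherits(noise, "noise_model"))
  k <- as.integer(clusters); n <- as.integer(samples); f <- as.integer(features)
  if (k < 2L) stop("need at least two clusters")
  if (n < k) stop("need at least one sample per cluster")
  if (f < 1L) stop("need at least one feature")
  if (!is.null(seed)) set.seed(seed)

  min_size <- max(1L, min(as.integer(min_cluster_size), n %/% k))
  repeat {
    truth <- sample.int(k, n, replace = TRUE)
    if (min(tabulate(truth, nbins = k)) >= min_size) break
  }

  m <- max(1L, round(informative_frac * f))
  baseline <- stats::rnorm(f, baseline_mean, baseline_sd)
  shifts <- matrix(0, nrow = f, ncol = k)
  shifts[seq_len(m), ] <- stats::rnorm(m * k, 0, shift_sd)
  S <- matrix(baseline, nrow = n, ncol = f, byrow = TRUE) +
    t(shifts[, truth, drop = FALSE])

  tau <- if (noise$tau_mean == 0) rep(0, f)
         else stats::rgamma(f, shape = noise$tau_shape,
                            scale = noise$tau_mean / noise$tau_shape)
  eps <- matrix(stats::rnorm(n * f), nrow = n, ncol = f)
  eps <- sweep(eps, 2L, tau, `*`) + noise$nu
  Y <- S + eps
  ids <- paste0("S", seq_len(n))
  dimnames(Y) <- dimnames(S) <- list(ids, paste0("F", seq_len(f)))
  names(truth) <- ids

  structure(list(
    Y = Y, S = S, truth = truth, tau = tau, noise = noise,
    config = list(clusters = k, samples = n, features = f,
                  noise = noise$level, seed = seed,
                  informative_frac = informative_frac, shift_sd = shift_sd,
                  baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                  min_cluster_size = min_size)
  ), class = "sim_dataset")
}

#' Deterministic Gaussian-blob fixture
#'
#' A minimal generator for tests and examples: `k` equal-sized spherical
#' Gaussian clusters in `f` dimensions with consecutive centers `separation`
#' apart along the first coordinate. With `sd = 0` and `f = 1` it reproduces
#' exact point configurations such as the four-point line `0, 1, 10, 11`.
#'
#' @param n,k,f Samples, clusters (`k <= n`), features.
#' @param separation Distance between consecutive cluster centers.
#' @param sd Within-cluster standard deviation (default 1; may be 0).
#' @param seed Optional seed.
#' @return A `"sim_dataset"` (signal equals the cluster centers).
#' @examples
#' blobs <- fixture_blobs(n = 4, k = 2, f = 1, separation = 10, sd = 0)
#' drop(blobs$S) # 0 0 10 10
#' @export
fixture_blobs <- function(n, k, f = 2L, separation = 6, sd = 1, seed = NULL) {
  n <- as.integer(n); k <- as.integer(k); f <- as.integer(f)
  if (k > n) stop("k must not exceed n")
  if (k < 1L || f < 1L) stop("k and f must be positive")
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  truth <- rep(seq_len(k), sizes)
  centers <- matrix(0, nrow = k, ncol = f)
  centers[, 1L] <- (seq_len(k) - 1L) * separation
  S <- centers[truth, , drop = FALSE]
  Y <- S + matrix(stats::rnorm(n * f, 0, sd), nrow = n, ncol = f)
  ids <- paste0("S", seq_len(n))
  dimnames(Y) <- dimnames(S) <- list(ids, paste0("F", seq_len(f)))
  names(truth) <- ids
  structure(list(
    Y = Y, S = S, truth = truth, tau = rep(sd, f),
    noise = noise_model(nu = 0, tau_mean = sd),
    config = list(clusters = k, samples = n, features = f, noise = "fixture",
                  separation = separation, sd = sd, seed = seed)
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d samples x %d features, %d clusters, noise = %s\n",
              nrow(x$Y), ncol(x$Y), x$config$clusters, x$config$noise))
  cat("cluster sizes:", paste(tabulate(x$truth), collapse = " "), "\n")
  invisible(x)
}
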