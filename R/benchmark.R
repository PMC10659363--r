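#' Describe a clustering method for the benchmark harness
#'
#' A method is a base clusterer plus an optional silhouette-refinement step.
#' Built-in bases are `"hierarchical_ward"` (agglomerative clustering with
#' Ward's linkage on Euclidean distances, tree cut at the true `k`) and
#' `"kmeans"` (the stats implementation with its defaults). `"none"` means
#' standalone multi-start SillyPutty and requires `refine = TRUE`. Any other
#' algorithm (PAM, CLARA, spectral, subspace, ...) plugs in through
#' `labeler`, a `function(data, k, d)` returning a label vector.
#'
#' @param name Display name used in records and summaries.
#' @param base One of `"none"`, `"hierarchical_ward"`, `"kmeans"`,
#'   `"external"`.
#' @param refine Refine the base labels with SillyPutty? Default `FALSE`.
#' @param labeler Labeling function for `base = "external"`.
#' @return A list of class `"method_spec"`.
#' @examples
#' method_spec("Hier+Silly", "hierarchical_ward", refine = TRUE)
#' @export
method_spec <- function(name, base = c("none", "hierarchical_ward", "kmeans", "external"),
                        refine = FALSE, labeler = NULL) {
  base <- match.arg(base)
  if (base == "none" && !refine) {
    stop("base = \"none\" is standalone SillyPutty and requires refine = TRUE")
  }
  if (base == "external" && !is.function(labeler)) {
    stop("base = \"external\" requires a labeler function(data, k, d)")
  }
  structure(list(name = name, base = base, refine = isTRUE(refine),
                 labeler = labeler), class = "method_spec")
}

#' The method roster used in the shipped comparison
#'
#' Standalone SillyPutty, the two built-in bases, and their
#' SillyPutty-refined hybrids.
#'
#' @return A list of [method_spec()] objects.
#' @export
default_methods <- function() {
  list(
    method_spec("SillyPutty", "none", refine = TRUE),
    method_spec("Hierarchical", "hierarchical_ward"),
    method_spec("Hier+Silly", "hierarchical_ward", refine = TRUE),
    method_spec("Kmeans", "kmeans"),
    method_spec("Kmeans+Silly", "kmeans", refine = TRUE)
  )
}

#' Run one method on one simulated dataset
#'
#' Obtains base labels (or runs multi-start SillyPutty when `base` is
#' `"none"`), optionally refines them on the Euclidean distance matrix, and
#' scores the result against the known truth with all five validity
#' indices. Every method receives the true number of clusters.
#'
#' @param dataset A `"sim_dataset"` (see [simulate_dataset()]).
#' @param spec A [method_spec()].
#' @param restarts Random restarts for standalone SillyPutty. Default 20.
#' @param seed Optional seed fixing the method's randomness.
#' @param control [refine_control()] for the refinement loop.
#' @param d Optional precomputed `"dist_matrix"` for `dataset$Y`; computed
#'   when absent (pass it when scoring several methods on one dataset).
#' @return A one-row data frame: `method`, the five indices of
#'   [evaluate_clustering()], plus refinement `iterations` and
#'   `termination` (`NA` for unrefined methods).
#' @export
run_method <- function(dataset, spec, restarts = 20L, seed = NULL,
                       control = refine_control(), d = NULL) {
  stopifnot(inherits(spec, "method_spec"), inherits(dataset, "sim_dataset"))
  data <- dataset$Y
  truth <- dataset$truth
  k <- length(unique(truth))
  if (is.null(d)) d <- euclidean_distances(data)
  if (!is.null(seed)) set.seed(seed)

  iterations <- NA_integer_
  termination <- NA_character_
  if (spec$base == "none") {
    fit <- silly_putty(d, k, restarts = restarts, control = control)
    pred <- labels(fit)
    iterations <- fit$iterations
    termination <- fit$termination
  } else {
    pred <- switch(spec$base,
      hierarchical_ward = stats::cutree(
        stats::hclust(stats::as.dist(unclass(d)), method = "ward.D2"), k = k),
      kmeans = stats::kmeans(data, centers = k)$cluster,
      external = spec$labeler(data = data, k = k, d = d)
    )
    if (spec$refine) {
      fit <- refine(d, pred, control = control)
      pred <- labels(fit)
      iterations <- fit$iterations
      termination <- fit$termination
    }
  }
  rec <- evaluate_clustering(data, pred, truth, d = d)
  cbind(data.frame(method = spec$name, stringsAsFactors = FALSE),
        rec, data.frame(iterations = iterations, termination = termination,
                        stringsAsFactors = FALSE))
}

#' Scaled profiles of the comparison study
#'
#' The full design runs the 27-row [design_grid()] with 19 replicates, the
#' printed sample and feature sizes, and 100 random restarts — hours of
#' compute. The `"reduced"` profile (the default elsewhere) keeps all 27
#' design rows but uses 2 replicates, a quarter of the samples, a 25th of
#' the features and 20 restarts, which preserves the qualitative structure
#' at desk scale.
#'
#' @param scale `"reduced"` or `"full"`.
#' @return A list with `grid`, `replicates`, `sample_div`, `feature_div`,
#'   `restarts`.
#' @export
study_profile <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(grid = design_grid(), replicates = 19L, sample_div = 1L,
         feature_div = 1L, restarts = 100L)
  } else {
    list(grid = design_grid(), replicates = 2L, sample_div = 4L,
         feature_div = 25L, restarts = 20L)
  }
}

#' Run the comparative study
#'
#' Simulates `replicates` datasets for every row of `grid` (seeded
#' deterministically from the master `seed`), runs every method on every
#' dataset, and returns one record per method and dataset. A failure in one
#' method on one dataset yields a flagged record (`error` column) rather
#' than aborting the study.
#'
#' @param methods List of [method_spec()]s. Default [default_methods()].
#' @param profile A [study_profile()] list; its components can be
#'   overridden individually.
#' @param grid,replicates,sample_div,feature_div,restarts Overrides for the
#'   corresponding `profile` entries.
#' @param seed Master seed for the whole study.
#' @param control [refine_control()] used everywhere.
#' @param verbose Print one line per dataset. Default `FALSE`.
#' @return A data frame of class `"study_records"`: one row per
#'   method x dataset with the design columns, the five indices,
#'   `iterations`, `termination` and `error`.
#' @export
run_study <- function(methods = default_methods(),
                      profile = study_profile("reduced"),
                      grid = profile$grid,
                      replicates = profile$replicates,
                      sample_div = profile$sample_div,
                      feature_div = profile$feature_div,
                      restarts = profile$restarts,
                      seed = NULL, control = refine_control(),
                      verbose = FALSE) {
  stopifnot(replicates >= 1L, nrow(grid) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n_ds <- nrow(grid) * replicates
  seeds <- matrix(sample.int(.Machine$integer.max, n_ds * (length(methods) + 1L)),
                  nrow = n_ds)

  records <- vector("list", n_ds * length(methods))
  slot <- 0L
  ds_i <- 0L
  for (g in seq_len(nrow(grid))) {
    row <- grid[g, ]
    for (rep_i in seq_len(replicates)) {
      ds_i <- ds_i + 1L
      sim <- simulate_dataset(
        clusters = row$clusters,
        samples = max(2L * row$clusters, round(row$samples / sample_div)),
        features = max(2L, round(row$features / feature_div)),
        noise = as.character(row$noise),
        seed = seeds[ds_i, 1L]
      )
      d <- euclidean_distances(sim$Y)
      if (verbose) {
        message(sprintf("dataset %d/%d (k=%d, %s noise, %d x %d)", ds_i, n_ds,
                        row$clusters, row$noise, nrow(sim$Y), ncol(sim$Y)))
      }
      for (m in seq_along(methods)) {
        slot <- slot + 1L
        rec <- tryCatch(
          cbind(run_method(sim, methods[[m]], restarts = restarts,
                           seed = seeds[ds_i, m + 1L], control = control, d = d),
                data.frame(error = NA_character_, stringsAsFactors = FALSE)),
          error = function(e) data.frame(
            method = methods[[m]]$name, asw = NA_real_, ari = NA_real_,
            nwss = NA_real_, entropy = NA_real_, perfect = NA,
            k_found = NA_integer_, iterations = NA_integer_,
            termination = NA_character_, error = conditionMessage(e),
            stringsAsFactors = FALSE)
        )
        records[[slot]] <- cbind(
          data.frame(dataset = row$dataset, replicate = rep_i,
                     clusters = row$clusters, noise = as.character(row$noise),
                     samples = row$samples, features = row$features,
                     stringsAsFactors = FALSE),
          rec)
      }
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  class(out) <- c("study_records", "data.frame")
  out
}

#' Summarize study records
#'
#' Per-method means of the four continuous indices, the Perfect
#' Classification Count (PCC), and per-factor breakdowns of the mean ARI by
#' cluster count, sample size, feature count and noise level. By default
#' replicate values are averaged within each design row first and the row
#' means are then averaged across the design (`"config_first"`), matching
#' how the shipped comparison aggregates replicates; `"overall"` averages
#' all records directly.
#'
#' @param records A `"study_records"` data frame from [run_study()].
#' @param average `"config_first"` (two-stage) or `"overall"`.
#' @return A list of class `"study_summary"` with `methods` (one row per
#'   method: `asw`, `ari`, `nwss`, `entropy`, `pcc`, `n_datasets`),
#'   `factors` (long data frame: `factor`, `level`, `method`, `ari`), and
#'   `average`.
#' @export
summarize_study <- function(records, average = c("config_first", "overall")) {
  average <- match.arg(average)
  if (nrow(records) == 0L) stop("no records to summarize")
  ok <- is.na(records$error)
  records <- records[ok, , drop = FALSE]
  idx_cols <- c("asw", "ari", "nwss", "entropy")

  config_means <- stats::aggregate(
    records[idx_cols],
    by = records[c("method", "dataset", "clusters", "noise", "samples", "features")],
    FUN = mean)

  base <- if (average == "config_first") config_means else records
  methods_tab <- stats::aggregate(base[idx_cols], by = base["method"], FUN = mean)
  pcc <- stats::aggregate(list(pcc = records$perfect), by = records["method"], FUN = sum)
  nds <- stats::aggregate(list(n_datasets = records$perfect), by = records["method"],
                          FUN = length)
  methods_tab <- merge(merge(methods_tab, pcc, by = "method"), nds, by = "method")
  methods_tab <- methods_tab[order(methods_tab$ari), , drop = FALSE]
  rownames(methods_tab) <- NULL

  factors <- do.call(rbind, lapply(
    c("clusters", "noise", "samples", "features"),
    function(fac) {
      agg <- stats::aggregate(list(ari = config_means$ari),
                              by = list(level = config_means[[fac]],
                                        method = config_means$method),
                              FUN = mean)
      cbind(data.frame(factor = fac, stringsAsFactors = FALSE), agg)
    }))

  structure(list(methods = methods_tab, factors = factors, average = average),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Study summary (%s averaging):\n",
              if (x$average == "config_first") "two-stage" else "overall"))
  print(format(x$methods, digits = digits), row.names = FALSE)
  invisible(x)
}
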