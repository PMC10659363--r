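test_that("method specs validate their contracts", {
  expect_error(method_spec("S", "none", refine = FALSE), "standalone")
  expect_error(method_spec("X", "external"), "labeler")
  expect_equal(method_spec("K", "kmeans")$base, "kmeans")
  roster <- default_methods()
  expect_true(any(vapply(roster, function(m) m$base == "none", logical(1))))
})

test_that("run_method scores built-in bases and hybrids on an easy fixture", {
  sim <- fixture_blobs(n = 24, k = 2, f = 2, separation = 30, sd = 1, seed = 8)
  d <- euclidean_distances(sim$Y)

  hier <- run_method(sim, method_spec("Hier+Silly", "hierarchical_ward",
                                      refine = TRUE), seed = 1, d = d)
  expect_equal(hier$ari, 1)
  expect_true(hier$perfect)
  expect_equal(hier$iterations, 0L)   # Ward already splits the blobs

  solo <- run_method(sim, method_spec("SillyPutty", "none", refine = TRUE),
                     restarts = 5, seed = 2, d = d)
  expect_equal(solo$ari, 1)
  expect_equal(solo$termination, "converged")

  # a base emitting the truth makes refinement a no-op fixed point
  oracle_base <- method_spec("Oracle", "external", refine = TRUE,
                             labeler = function(data, k, d) sim$truth)
  fixed <- run_method(sim, oracle_base, seed = 3, d = d)
  expect_equal(fixed$iterations, 0L)
  expect_equal(fixed$ari, 1)
})

test_that("standalone spec equals silly_putty plus metrics", {
  sim <- fixture_blobs(n = 20, k = 2, f = 2, separation = 25, sd = 1, seed = 12)
  d <- euclidean_distances(sim$Y)
  rec <- run_method(sim, method_spec("SillyPutty", "none", refine = TRUE),
                    restarts = 4, seed = 99, d = d)
  set.seed(99)
  fit <- silly_putty(d, 2, restarts = 4)
  direct <- evaluate_clustering(sim$Y, labels(fit), sim$truth, d = d)
  expect_equal(rec$ari, direct$ari)
  expect_equal(rec$asw, direct$asw)
  expect_equal(rec$iterations, fit$iterations)
})

test_that("a small custom study produces the expected record table", {
  grid <- design_grid()[c(12, 23), ]   # two low-noise rows
  methods <- list(method_spec("Hierarchical", "hierarchical_ward"),
                  method_spec("Hier+Silly", "hierarchical_ward", refine = TRUE))
  rec <- run_study(methods = methods, grid = grid, replicates = 1,
                   sample_div = 20, feature_div = 100, restarts = 5, seed = 42)
  expect_s3_class(rec, "study_records")
  expect_equal(nrow(rec), 2L * 2L)       # 2 datasets x 2 methods
  expect_true(all(is.na(rec$error)))
  expect_true(all(rec$ari >= -0.5 & rec$ari <= 1))

  # same master seed reproduces the table exactly
  rec2 <- run_study(methods = methods, grid = grid, replicates = 1,
                    sample_div = 20, feature_div = 100, restarts = 5, seed = 42)
  expect_identical(rec, rec2)
})

test_that("per-method failures are flagged, not fatal", {
  grid <- design_grid()[12, ]
  bad <- method_spec("Broken", "external", labeler = function(data, k, d)
    stop("boom"))
  rec <- run_study(methods = list(bad, method_spec("Kmeans", "kmeans")),
                   grid = grid, replicates = 1, sample_div = 20,
                   feature_div = 100, seed = 3)
  expect_equal(nrow(rec), 2L)
  expect_equal(sum(!is.na(rec$error)), 1L)
  expect_match(rec$error[!is.na(rec$error)], "boom")
})

test_that("summaries aggregate correctly and ignore record order", {
  grid <- design_grid()[c(12, 23), ]
  methods <- list(method_spec("Hierarchical", "hierarchical_ward"),
                  method_spec("Kmeans", "kmeans"))
  rec <- run_study(methods = methods, grid = grid, replicates = 2,
                   sample_div = 20, feature_div = 100, seed = 11)
  s <- summarize_study(rec)
  expect_setequal(s$methods$method, c("Hierarchical", "Kmeans"))
  expect_true(all(s$methods$pcc <= s$methods$n_datasets))
  expect_true(all(s$methods$entropy >= 0 & s$methods$entropy <= 1))

  shuffled <- rec[sample(nrow(rec)), ]
  class(shuffled) <- class(rec)
  s2 <- summarize_study(shuffled)
  ord <- order(s$methods$method); ord2 <- order(s2$methods$method)
  expect_equal(s$methods[ord, ], s2$methods[ord2, ], ignore_attr = TRUE)

  # restricting to one method equals recomputation from its records alone
  only_k <- rec[rec$method == "Kmeans", ]
  class(only_k) <- class(rec)
  sk <- summarize_study(only_k)
  expect_equal(sk$methods$ari,
               s$methods$ari[s$methods$method == "Kmeans"])

  # two-stage averaging equals overall averaging when replicates are balanced
  config_first <- summarize_study(rec, "config_first")$methods
  overall <- summarize_study(rec, "overall")$methods
  expect_equal(config_first$ari, overall$ari[match(config_first$method,
                                                   overall$method)],
               tolerance = 1e-12)

  # single-record summary is that record
  one <- rec[1, ]; class(one) <- class(rec)
  expect_equal(summarize_study(one)$methods$ari, rec$ari[1])
  expect_error(summarize_study(rec[0, ]), "no records")
})
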