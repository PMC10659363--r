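test_that("contingency tables tally co-occurrences", {
  tab <- contingency(c(1, 1, 1, 2), c(1, 1, 2, 2))
  expect_equal(unname(unclass(tab)[, ]), matrix(c(2, 0, 1, 1), 2, 2))
  expect_equal(attr(tab, "n"), 4L)
  expect_equal(unname(attr(tab, "row_sums")), c(3, 1))

  diag_tab <- contingency(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(sum(unclass(diag_tab)[, ] > 0), 3L)

  one_row <- contingency(rep(1, 5), c(1, 1, 2, 2, 3))
  expect_equal(nrow(one_row), 1L)
  expect_error(contingency(1:3, 1:4), "length")
})

test_that("adjusted Rand index matches hand values and its symmetry/permutation laws", {
  expect_equal(adjusted_rand_index(c(1, 1, 1, 2), c(1, 1, 2, 2)), 0)
  lab <- c(1, 1, 2, 2, 3)
  expect_equal(adjusted_rand_index(lab, lab), 1)
  expect_equal(adjusted_rand_index(lab, c("b", "b", "c", "c", "a")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1, 2), c(1, 1, 2, 2)),
               adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 2)))
})

test_that("adjusted Rand index matches the pair-counting oracle on random instances", {
  set.seed(23)
  for (trial in 1:30) {
    n <- sample(4:25, 1)
    pred <- sample.int(sample(2:4, 1), n, replace = TRUE)
    truth <- sample.int(sample(2:4, 1), n, replace = TRUE)
    expect_equal(adjusted_rand_index(pred, truth), oracle_ari(pred, truth),
                 tolerance = 1e-12)
    expect_lte(adjusted_rand_index(pred, truth), 1)
  }
})

test_that("adjusted Rand index agrees with mclust's implementation", {
  skip_if_not_installed("mclust")
  set.seed(29)
  for (trial in 1:10) {
    pred <- sample.int(3, 20, replace = TRUE)
    truth <- sample.int(4, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(pred, truth),
                 unname(mclust::adjustedRandIndex(pred, truth)),
                 tolerance = 1e-12)
  }
})

test_that("clustering entropy matches hand-computed tables and stays in [0, 1]", {
  expect_equal(clustering_entropy(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  # one mixed cluster of 3: (3/4) * H(2/3, 1/3) / log 2
  expect_equal(clustering_entropy(c(1, 1, 1, 2), c(1, 1, 2, 2)),
               (3 / 4) * (-(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3)) / log(2),
               tolerance = 1e-12)
  # a refinement of the truth is pure: entropy 0
  expect_equal(clustering_entropy(c(1, 2, 3, 4), c(1, 1, 2, 2)), 0)
  # everything in one predicted cluster, balanced truth of K = 2: maximal
  expect_equal(clustering_entropy(rep(1, 4), c(1, 1, 2, 2)), 1)
  expect_error(clustering_entropy(c(1, 2), c(1, 1)), "fewer than two")

  set.seed(37)
  for (trial in 1:20) {
    n <- sample(4:30, 1)
    pred <- sample.int(3, n, replace = TRUE)
    truth <- sample.int(3, n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    e <- clustering_entropy(pred, truth)
    expect_gte(e, 0); expect_lte(e, 1)
    # label-permutation invariance in both arguments
    expect_equal(clustering_entropy(c("x", "y", "z")[pred], truth), e)
    expect_equal(clustering_entropy(pred, c(7, 5, 9)[truth]), e)
  }
})

test_that("within-group sum of squares matches hand arithmetic", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(wss(X, c(1, 1, 2, 2)), 1)
  expect_equal(wss(X, 1:4), 0)                       # singletons: no deviation
  expect_equal(wss(matrix(3, 5, 2), rep(1, 5)), 0)   # identical points
  # mirrors kmeans' own objective at its fitted labels
  set.seed(41)
  Y <- rbind(matrix(rnorm(30), 15, 2), matrix(rnorm(30, 5), 15, 2))
  km <- kmeans(Y, 2)
  expect_equal(wss(Y, km$cluster), km$tot.withinss, tolerance = 1e-8)
})

test_that("normalized WSS is the plain ratio with an exact unit diagonal", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  truth <- c(1, 1, 2, 2)
  expect_identical(normalized_wss(X, truth, truth), 1)
  expect_equal(normalized_wss(X, c(1, 1, 1, 2), truth), (546 / 9) / 1,
               tolerance = 1e-12)
  expect_gt(normalized_wss(X, c(1, 2, 1, 2), truth), 0)
  expect_error(normalized_wss(matrix(1, 4, 1), c(1, 1, 2, 2), c(1, 1, 2, 2)),
               "zero")
})

test_that("no labeling with the true cluster count beats the k-means optimum by WSS", {
  set.seed(43)
  X <- matrix(rnorm(14), 7, 2)
  best_km <- min(replicate(20, kmeans(X, 2, nstart = 5)$tot.withinss))
  for (lab in all_labelings(7, 2)) {
    if (length(unique(lab)) == 2L) expect_gte(wss(X, lab) + 1e-9, best_km)
  }
})

test_that("perfect classification is exact partition identity up to label names", {
  truth <- c(1, 1, 2, 2, 3)
  expect_true(is_perfect(c("b", "b", "a", "a", "z"), truth))
  moved <- c(1, 1, 2, 3, 3)
  expect_false(is_perfect(moved, truth))
  expect_false(is_perfect(rep(1, 5), truth))
  # consistency with the ARI = 1 characterization
  expect_equal(adjusted_rand_index(c("b", "b", "a", "a", "z"), truth), 1)
})

test_that("evaluate_clustering bundles the five indices coherently", {
  set.seed(47)
  sim <- fixture_blobs(n = 30, k = 3, f = 2, separation = 20, sd = 0.5, seed = 3)
  rec <- evaluate_clustering(sim$Y, sim$truth, sim$truth)
  expect_equal(rec$ari, 1)
  expect_equal(rec$entropy, 0)
  expect_identical(rec$nwss, 1)
  expect_true(rec$perfect)
  expect_equal(rec$k_found, 3L)
  expect_gt(rec$asw, 0.8)
})
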