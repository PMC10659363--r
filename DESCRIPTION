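Package: sillyputty
Title: Cluster Refinement by Silhouette-Width Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the SillyPutty clustering heuristic: iterative
    reassignment of the observation with the most negative silhouette width to
    its nearest other cluster, until every silhouette width is non-negative.
    Provides a multi-start standalone clusterer, a refinement step for labels
    produced by any other method (hybrid clustering), external and internal
    cluster validity indices (adjusted Rand index, normalized cluster-purity
    entropy, within-group sum of squares and its normalized form, perfect
    classification flag), a simulator for log-scale gene-expression-like data
    with known cluster structure and tunable additive Gaussian noise, and a
    benchmark harness that runs base clusterers and their SillyPutty-refined
    hybrids over a factorial simulation design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr
Config/testthat/edition: 3
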