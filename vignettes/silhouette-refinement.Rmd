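---
title: "Silhouette-width refinement: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silhouette-width refinement: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sillyputty)
```

## The procedure

Given a set of $n$ samples with pairwise dissimilarities $D$ and a partition
into clusters, the silhouette width of sample $i$ is

$$ s_i \;=\; \frac{b_i - a_i}{\max(a_i, b_i)} \in [-1, 1], $$

where $a_i$ is the mean dissimilarity between $i$ and the other members of
its own cluster (cohesion) and $b_i$ is the smallest mean dissimilarity
between $i$ and the members of any other cluster (separation). A negative
$s_i$ says sample $i$ sits closer, on average, to another cluster than to its
own — a direct, per-sample certificate of misassignment.

The SillyPutty heuristic turns that certificate into a clustering move:
repeatedly find the sample with the most negative silhouette width and
reassign it to the cluster attaining its $b_i$, recomputing the full
silhouette profile after each single move. The loop stops when

1. every $s_i \ge 0$ (**converged**),
2. a maximum number of reassignments is reached (**max_iterations**),
3. the same silhouette vector reappears within a recent window, indicating an
   oscillation (**cycle_detected**), or
4. a move would leave fewer than two clusters (**degenerate**).

`refine()` implements this loop from any starting labels. `silly_putty()`
turns it into a standalone clusterer by running the loop from (by default)
100 uniformly random assignments of $k$ clusters and keeping the run with the
largest final average silhouette width (ASW). Because the loop accepts
arbitrary starts, it also composes with any existing clusterer: run the base
method, then `refine()` its labels — the *hybrid* usage.

Assumptions worth stating: the procedure only sees the dissimilarity matrix,
so it inherits whatever geometry the chosen metric imposes (we compute
Euclidean distances by default); optimizing ASW implicitly prefers compact,
well-separated, roughly convex clusters; and the number of clusters is an
input — the package never selects $k$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `restarts` | 100 | random starts of the standalone clusterer; the reduced study profile uses 20 |
| `max_iterations` | 1000 | cap on single-point reassignments per start |
| `cycle_window` | 10 | silhouette vectors remembered for oscillation detection |
| `rounding_digits` | 12 | decimals used when comparing silhouette vectors |

The cap and window defaults are package choices: the halting conditions are
part of the algorithm's definition, but no canonical values exist for them.
A window of 10 comfortably covers the short oscillations single-point moves
can produce, and 1000 moves is far beyond what converging runs need (the
worst random starts in the shipped study use a few hundred). Cycle detection
compares silhouette vectors rounded to 12 decimals so that floating-point
jitter cannot mask a revisited state.

## Numerical conventions and tie-breaks

* **Singleton clusters.** $a_i$ is undefined for a cluster of one; we adopt
  Rousseeuw's convention $s_i = 0$, matching `cluster::silhouette`. The
  cohesion is stored as 0 with a `singleton` flag and the $s_i = 0$ override
  is applied before the $(b-a)/\max(a,b)$ expression is evaluated, so no
  0/0 can occur. A point with $s_i = 0$ is never the most-negative point,
  which has the useful consequence that the refinement loop never moves the
  sole member of a cluster.
* **Ties.** The worst point is the first index attaining the minimum; a
  separation tie between clusters resolves to the smallest cluster
  identifier; the multi-start winner on an ASW tie is the earliest restart.
  All runs are therefore exactly reproducible.
* **Empty clusters.** If a move empties its donor cluster the cluster is
  dropped and the effective $k$ decreases; if only one cluster would remain
  the run stops as degenerate. (Given the singleton convention this can only
  be triggered by pathological inputs, but the guard is kept.)
* **Validation.** Distance matrices must be square, non-negative,
  zero-diagonal and symmetric to $10^{-9}$; asymmetries inside that
  tolerance are averaged away, larger ones are errors.
* **Degenerate ARI.** When the Hubert–Arabie adjustment denominator is zero
  (e.g. both partitions trivial) the index is defined as 1 if the partitions
  agree exactly and 0 otherwise. Pair counts are accumulated as exact
  integers so that ARI of identical partitions is exactly 1.
* **Entropy.** The cluster-impurity entropy is normalized by $\log K$ with
  $K$ the number of *true* clusters, uses $0 \log 0 = 0$, and weights
  predicted clusters by their size; it needs $K \ge 2$.
* **Normalized WSS.** Defined as the plain ratio
  $\mathrm{WSS}(\text{pred})/\mathrm{WSS}(\text{truth})$. Values below 1 are
  possible — a fitted labeling can have a smaller within-group sum of squares
  than the generative truth — so we do not clamp the ratio to $[1, \infty)$.

## What the simulator emulates — and what it does not

`simulate_dataset()` produces samples-by-features matrices on the log2 scale
that behave like clustered expression data: observed values are
$Y = S + \varepsilon$ where $S$ is a noise-free signal and the additive
noise has mean $\nu = 0.1$ and per-feature standard deviation
$\tau_g \sim \Gamma$ with mean set by the named noise level. The signal model
is deliberately simple: every feature has a global baseline
$\mathcal N(6, 1.5^2)$; 10% of features are informative, receiving
independent cluster-specific shifts $\mathcal N(0, 1)$; cluster memberships
are equal-probability multinomial, resampled until every cluster has at
least 5 members.

The gamma means for the three noise levels — 0.3 (low), 0.9 (medium), 1.8
(high), shape 4, drawn once per feature — are this package's calibration:
they were chosen so that low-noise datasets are recovered perfectly by both
k-means and the standalone refiner at the reduced problem sizes below, while
the levels order cleanly by difficulty (low > medium > high recovered ARI).
All of them are exposed as arguments.

Real expression data have features the emulation omits: correlated gene
blocks and pathway structure, heavy-tailed and count-derived noise, unequal
cluster prevalences, batch effects, and dropout. Tests passing on these
simulations therefore demonstrate correctness of the algorithms and the
qualitative difficulty trends, not performance on any particular real
dataset.

## The comparative study and its problem sizes

`run_study()` crosses the 27-row factorial design (cluster count 3/6/12,
600/1000 samples, 5000/10000 features, low/medium noise fully crossed plus
one high-noise cell per cluster count) with replicate simulations, runs each
method on each dataset with the true $k$, and scores five indices: ASW, ARI,
normalized entropy, normalized WSS, and the perfect-recovery flag whose
study-wide count is the Perfect Classification Count. Replicates are averaged
within a design row first, then across rows (`summarize_study()` can also
average all records directly; with balanced designs the two agree).

The shipped default is the `"reduced"` profile: 2 replicates, samples
divided by 4 (150/250), features divided by 25 (200/400), 20 restarts —
about three minutes on one core, against hours for the full-scale profile
(19 replicates, full sizes, 100 restarts), which remains available via
`study_profile("full")`. One caveat of scaling down: with per-feature
additive noise the ratio of between-centroid separation to distance
fluctuations grows like $\sqrt{F}$, so a 25-fold feature reduction makes
medium- and high-noise datasets intrinsically harder than their full-scale
counterparts. The reduced study consequently reports lower mean ARIs than a
full-scale run would, while preserving every ordering the comparison is
about (hybrids at least as good as their bases, refinement of random starts
competitive with the best base methods, difficulty monotone in noise and
cluster count).

## Known limitations

* One point moves per iteration with a full $O(n^2)$ profile recomputation;
  incremental updates and multi-point moves would be faster but are left out
  to keep the reference behavior simple and exactly reproducible.
* No automatic choice of $k$, no non-Euclidean built-in metrics (precomputed
  dissimilarities of any origin are accepted), and no approximate silhouette
  for very large $n$.
* PAM, CLARA, spectral and subspace baselines are not bundled; they plug in
  through `method_spec(base = "external", labeler = ...)`.
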