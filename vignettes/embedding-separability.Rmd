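---
title: "Measuring 2D-vs-3D embedding separability"
author: "embedsep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 2D-vs-3D embedding separability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embedsep)
```

## The question this package answers

Dimension-reduction methods (UMAP, tSNE, PHATE, ...) place single cells in
2 or 3 coordinates. A 3D embedding can keep apart cell populations that a 2D
embedding flattens onto each other - but a viewer looking at a 3D plot on a
screen always sees a 2D projection of it. The fair comparison is therefore:
*over all viewing angles of the 3D embedding, does the best 2D view mix a
pair of populations less than the native 2D embedding does?*

`embedsep` operationalizes this with two mixing scores, both evaluated on
orthographic projections:

**Entropy score.** A rectangular grid of sectors is placed over the 2D
points of the two populations. In each sector with population proportions
$p_1, p_2$ the Shannon index

$$SI = -\sum_{i=1}^{R} p_i \ln p_i, \qquad R = 2$$

is computed (0 for a pure sector, $\ln 2$ for a perfectly mixed one) and
the sector values are summed. Because the score depends on where the grid
happens to fall, the grid is shifted stepwise over a lattice of offsets and
the lowest total is kept.

**Hull score.** Convex hulls (Quickhull) of the two projected populations
are intersected (convex polygon clipping) and the intersection area is
expressed as a percentage of the smaller hull's area.

For a 3D embedding, both scores are minimized over a deterministic set of
viewing directions (default 2048, matching the published exhaustive
search); the minimum is compared against the score of the native 2D
embedding. The all-pairs driver `pairwise_matrix()` reports
`score_3D_best - score_2D` for every population pair, so *negative entries
mean the third dimension helped*.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_angles` | 2048 | directions on the sphere | published exhaustive-search count; Fibonacci spiral, deterministic |
| `sectors_per_axis` | 10 x 10 | sectors | grid coarse enough for multiple cells per sector at typical pair sizes, fine enough to localize overlap; not stated in the source method, chosen here |
| `n_shift_steps` | 5 | lattice per axis | shift fractions k/5 including the unshifted grid; bounded cost |
| `min_pop_size` | 10 | cells | hulls/grids over a handful of cells are noise; smaller populations are dropped and listed in metadata |
| `N_top_markers` | 250 | genes | published heatmap default |
| `K_top_edges` | 130 | edges | published network default |
| `n_trajectory_clusters` | 4 | clusters | published trajectory partition |
| `n_pseudotime_bins` | 10 | groups | published colour-group count |

Design choices where the method description was genuinely open:

* **Angle sampling.** Only the count (2048) is published, not the scheme.
  We use a golden-angle Fibonacci spiral: deterministic, near-uniform, and
  identical for both metrics so they share one tested code path. Antipodal
  directions are retained (projections from $\pm v$ differ only by a
  reflection) so the default matches the printed 2048.
* **In-plane orientation.** An orthographic projection needs an "up" rule;
  we project the world z-axis onto the viewing plane (world x-axis fallback
  within ~2.5 degrees of the poles). Only the entropy grid is sensitive to
  in-plane rotation, and a fixed rule makes reruns bit-identical.
* **Grid placement.** The bounding box is computed over the *pair subset*,
  per projection, so sector size adapts to the pair's extent and scores are
  comparable across pairs. Sectors are half-open; points on the max edge are
  clamped into the last sector; a shifted grid gains one extra sector
  row/column to catch points below the shifted origin. Degenerate (zero
  width) boxes are inflated by 1e-9.
* **Ties.** Equal scores keep the first-evaluated candidate (row-major shift
  order, lowest angle index), so results are reproducible run to run.
* **Degenerate hulls.** Fewer than 3 distinct or collinear points give area
  0; the overlap of a pair whose smaller hull is degenerate is defined as
  0% and flagged, keeping pairwise matrices total.
* **Exactly touching hulls** (shared edge/vertex) intersect with area 0.

## In-session statistics

The selection statistics mirror what the interactive tool computes on user-
captured cell groups:

* `wilcoxon_rank_sum()` - rank-sum test with midranks. Exact p via a
  dynamic-programming enumeration of the null distribution when
  $n_1 + n_2 \le 20$ and there are no ties; otherwise the normal
  approximation with tie and continuity corrections. Authored in-package
  (not delegated), as is `bh_adjust()` (Benjamini-Hochberg step-up).
* `differential_expression()` ranks genes by p (ties: larger absolute mean
  difference, then name); more than two groups are handled one-vs-rest.
* `select_and_order_markers()` - top-N genes ordered by the leaf order of
  complete-linkage hierarchical clustering on Euclidean distances of
  per-gene standardized expression (linkage not stated in the source;
  complete linkage is the convention of the surrounding R ecosystem).
* `network_edges()` - the default "rho" score is the transparent
  proportionality statistic $\rho = 2\,\mathrm{cov}(a,b) /
  (\mathrm{var}\,a + \mathrm{var}\,b)$ on log1p expression. It is a
  documented stand-in for the rho of compositional-proportionality
  packages, *not* numerically identical to them; Pearson correlation is the
  alternative. Constant genes are excluded and reported.
* `partition_for_trajectory()` - seeded k-means (10 restarts) producing the
  input partition for an external trajectory-inference tool; the tool
  itself is out of scope. `pseudotime_bins()` and
  `correlate_to_pseudotime()` consume its output: ranked equal-size bins
  (earliest bins take the remainder cells; ties broken by cell ID) and
  Pearson correlation ranking (constant genes get 0).

## The synthetic world

All tests run on the built-in generator, not on downloaded data.

* `make_blobs_3d()` draws isotropic Gaussian blobs at given centers -
  coordinates are simulated directly rather than by running UMAP/tSNE on
  simulated expression, keeping tests fast and deterministic.
* `make_axis_hidden_pair()` builds the benchmark scenario: two populations
  with identical x-y distributions, means 10 sigma apart along z, n = 200
  each. Its 2D embedding is the (x, y) projection. By construction the pair
  overlaps in 2D while some sampled direction views the gap edge-on, so the
  3D best-angle entropy and hull overlap both reach 0.
* `make_expression()` draws negative-binomial counts (log-normal per-gene
  baseline means, dispersion 2, base mean 2), multiplies DE-gene means by
  `exp(effect)` in the affected population, and log1p-normalizes - the
  conventional scRNA-seq noise model, adequate for rank-based tests. It
  deliberately omits dropout, library-size gradients and batch effects.

A green test on this world therefore establishes that the metrics behave as
specified on well-controlled geometry and count noise; it does **not**
establish anything about any particular biological dataset, about
embeddings produced by real DR runs (which have non-Gaussian shapes), or
about equivalence with the original interactive tool's binaries.

## Numerical conventions

* Natural logarithms (nats) throughout the entropy score.
* Coordinates serialize with 17 significant digits, so file round-trips are
  bit-identical.
* Proportions passed to `shannon_index()` must sum to 1 within 1e-9.
* The SQLite expression store keeps only non-zero triples, indexed by gene,
  with a recorded schema version. The schema is this package's own
  documented dialect - byte-compatibility with the original tool's loader
  is explicitly not claimed (and is unverifiable offline).
* Intersection areas are clamped to `[0, min(hull areas)]` to absorb
  floating-point jitter from clipping.

## Known limitations

* The entropy score grows with the number of occupied sectors, so totals
  are comparable between pairs only under a fixed grid resolution.
* Fibonacci direction sets for different `n` are not nested; enlarging `n`
  lowers the minimum in expectation but is not formally monotone direction
  by direction (the all-pairs driver documents this).
* The "rho" network score is a stand-in, as above.
* No statistical test is attached to entropy/hull differences; the package
  reports effect directions and magnitudes only.

## A worked run

```{r, eval = FALSE}
pair <- make_axis_hidden_pair(separation = 10, sigma = 1, n_per_pop = 200,
                              seed = 1)
angles <- sample_viewing_angles(2048)
entropy_overlap_pair_2d(pair$embedding2d, pair$celltypes, "pop1", "pop2")
entropy_overlap_pair_3d(pair$embedding3d, pair$celltypes, "pop1", "pop2",
                        angles = angles)
m <- pairwise_matrix(pair$embedding2d, pair$embedding3d, pair$celltypes,
                     method = "hull")
summarize_matrix(m)
```

The same analysis is scriptable end-to-end through the CLI dispatcher:

```{r, eval = FALSE}
embedsep_main(c("simulate", "--preset", "fig2", "--seed", "1",
                "--out", "bundle"))
embedsep_main(c("compare", "--bundle", "bundle", "--method", "hull",
                "--out", "results"))
```
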