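---
title: "Trimmed cell clusters and marker-set robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trimmed cell clusters and marker-set robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimcells)
```

## The problem

Marker-gene selection in scRNA-seq rests on an unsupervised clustering of
cells, and clusters routinely contain cells that sit at the periphery —
biological extremes, transition states, or simply mis-assigned cells. A
handful of such border cells can carry a marker gene over the significance
threshold, or keep one under it, so conclusions drawn from a single run
inherit an invisible dependence on them. `trimcells` makes that dependence
visible with the logic of trimmed estimators from robust statistics: run
the analysis once on the full data, once after removing a small fraction of
the most extreme cells per cluster, and quantify how much the marker
selection moved. Two analyses instead of hundreds of bootstrap replicates.

## Identifying extreme cells

Extremity is measured in the *high-dimensional* normalized expression
space, not in a 2-D embedding. For each cell $i$ of a cluster, the
Euclidean distances $D_{j,i}$ to its $k$ nearest within-cluster neighbours
are computed, and the statistic is the minimum

$$\min D_i = \min_{j = 1, \dots, k} D_{j,i},$$

the distance to the single closest cell of the same cluster. A cell whose
*nearest* neighbour is already far away lies in a sparsely populated region
of its cluster. Cells with $\min D_i > Q_{1-\alpha}$, where $Q_{1-\alpha}$
is the empirical $(1-\alpha)$ quantile of the cluster's $\min D$ values,
are flagged `extreme`; the rest are `core`. $\alpha$ is the trimming
fraction (`keep_frac` $= 1 - \alpha$ in `trim_dist()`), and $\alpha = 0.1$
with $k = 30$ is the conventional operating point.

Parameter roles:

* `k` (default 30) sets how much local structure feeds each distance; the
  statistic itself uses only the closest neighbour, so `k` mainly matters
  through the stored neighbour profile and small-cluster handling.
* `alpha` in $[0, 1)$ is the per-cluster trimming fraction, in units of
  cells. At $\alpha = 0$ nothing is flagged.

Numerical conventions, chosen once and applied everywhere: quantiles are
type-7 (linear interpolation, the R default); the flagging rule is a
*strict* inequality, so ties at the threshold stay core; clusters with
$c \le k$ cells use an effective neighbourhood of $c - 1$; singleton
clusters get an infinite sentinel distance, a warning, and are never
trimmed. Distances are computed on the normalized (not z-scaled) values of
the pipeline's HVG subset by default — `feature_set = NULL` switches to all
genes — because the trimming statistic should see the same space the
analysis works in, and z-scaling would let near-constant genes dominate
the metric.

## The embedding-level variant

`trim_hull()` retains the older geometric construction: per cluster, an
alpha hull of the cells' 2-D embedding coordinates, each cell's minimum
distance to its own cluster's boundary, and a quantile cutoff
(`outlier_quantile`) *below* which cells are flagged — cells hugging the
border. `hull_alpha` is the concavity radius: large values converge to the
convex hull, small ones trace tight, concave outlines. The boundary is
built from Delaunay edges through which an empty disc of radius
`hull_alpha` passes (the alpha-extreme-edge criterion), with the exact
hull's arcs represented by their chords; degenerate clusters (fewer than
three points, collinear) fall back to their convex hull with a warning.

This variant exists for parity and visual inspection, but the
high-dimensional route is the recommended default: the locational-shift
simulations below show that dimension reduction moves individual extreme
cells away from the border, so 2-D geometry is not a faithful proxy for
high-dimensional extremity.

## Quantifying robustness

With $S_\mathrm{full}$ and $S_\mathrm{trim}$ the marker sets of a cluster
from the full and trimmed analyses,

$$S_1 = S_\mathrm{full} \setminus S_\mathrm{trim}, \quad
  S_2 = S_\mathrm{full} \cap S_\mathrm{trim}, \quad
  S_3 = S_\mathrm{trim} \setminus S_\mathrm{full},$$

and $P_i = 100\,|S_i| / m$ with $m = |S_\mathrm{full} \cup
S_\mathrm{trim}|$. Large $P_2$: the cluster's markers are robust. Large
$P_1$: the full-data markers leaned on the border cells. Large $P_3$:
trimming changed the selection wholesale. When $m = 0$ all three are
defined as 0 and the cluster is annotated `empty`. `trim_effect()` runs
the whole contrast under two analysis variants (two normalizations, two
HVG counts, ...) and emits the variant-blocked heatmap table;
`breakdown_profile()` tracks, against the fixed baseline
$S_\mathrm{full}$, the retention $100\,|S_\mathrm{full} \cap
S_\mathrm{trim}(\alpha)| / |S_\mathrm{full}|$ across trimming levels
(default 0–40%), the analogue of a breakdown-point analysis. Retention is
*not* monotone by construction, since markers are recomputed at each
level; the denominator $|S_\mathrm{full}|$ is deliberately different from
the $P_2$ denominator $m$.

Cluster labels are fixed before trimming and trimming never re-clusters,
so clusters are matched by label identity between the full and trimmed
runs.

## Marker detection

`find_all_markers()` is a self-contained one-vs-rest Wilcoxon rank-sum
detector in the style of the standard single-cell toolkits: genes are
prefiltered on detection rate (`min_pct = 0.1` in either group) and on
fold change (`log2fc_min = 0.25`, computed as
$\log_2[(\mathrm{mean}(\mathrm{expm1}(x_\mathrm{in})) + 1) /
(\mathrm{mean}(\mathrm{expm1}(x_\mathrm{out})) + 1)]$, the pseudocount-on-
de-logged-means convention), tested two-sided with the tie-corrected
normal approximation (no continuity correction), and Bonferroni-adjusted
over the genes actually tested in that cluster. When both groups have at
most ten cells the p-value comes from exhaustive enumeration over all
group assignments instead. Bonferroni rather than BH mirrors the default
of the reference workflow this detector stands in for; the test suite
checks the detector's null calibration directly (raw $p \le 0.05$ rate of
$0.05 \pm 0.02$ under permuted labels).

## The standard pipeline

`run_standard_pipeline()` provides reproducible inputs for the trimming
core: feature-count cell filters (defaults 200–2500 detected genes, the
droplet-QC convention), `log_normalize()` (library-size scaling to
10 000 followed by `log1p`) or `clr_normalize()` (centered log-ratio
within each cell across genes — the margin is per cell, symmetric to the
library-size normalization), vst-style HVG selection (loess trend of
log-variance on log-mean, standardized values clipped at $\sqrt{n}$; a
plain dispersion ranking when too few variable genes exist to fit a
trend), per-gene z-scaling, PCA, Louvain communities on a Jaccard-weighted
shared-nearest-neighbour graph, and a seeded t-SNE. Clustering and
embedding are deliberately delegated to established implementations —
they are not this package's contribution — and every stochastic step
consumes the single `seed` in the config, making runs bitwise repeatable.

## What the synthetic data emulates

Two generators make every claim testable without external downloads.

`gen_gaussian_cloud()` draws seeded multivariate-normal cell clouds for
the locational-shift question: a dense high-correlation 3-D scenario
(pairwise correlation 0.9, so the leading axis carries
$(1 + 2\cdot0.9)/3 \approx 93\%$ of the variance) and 100-D scenarios
with AR-1 ($\rho = 0.5$) or block (4 blocks, within-block correlation
0.6) covariance. The magnitudes are package choices — "high" and "small"
correlation are not otherwise pinned down — and are configurable.
`locational_shift_score()` then asks what fraction of the top-5%
Mahalanobis-extreme cells land in the top-10% border region of a 2-D
embedding: 1 means perfect concordance, and an embedding independent of
extremity gives $2q = 0.1$ in expectation.

`gen_planted_dataset()` produces negative-binomial counts for several
clusters with three known truths: border cells (a fraction of each
cluster drawn with variance-inflated log-normal expression noise, which
pushes them to the cluster periphery without changing its identity),
robust markers (uniformly over-expressed across their cluster), and
optionally one fragile marker per cluster expressed only in that
cluster's border cells. Defaults are the package's study conditions,
chosen once: 3 clusters × 100 cells, 500 genes with log-normal baseline
means (median 2, `sdlog` 1 — a flat baseline would make the HVG trend
unidentifiable), 20 markers per cluster at 8-fold elevation, core noise
SD 0.5 on the log scale, 10% border cells with variance inflation ×4, NB
size 10. Under these conditions the kNN trimmer recovers planted border
cells with precision and recall well above the 10% chance level, robust
clusters keep $P_2 \ge 90$, and fragile markers land in $S_1$ — the test
suite computes all of these.

What the generator does *not* emulate: ambient RNA, doublets, batch
effects, library-size gradients, or continuous differentiation
trajectories. A passing suite therefore demonstrates the machinery's
correctness and the claimed qualitative behaviours on clean cluster
structure, not performance on any particular real tissue.

## Numerical and design choices

* Type-7 quantiles and strict threshold inequalities throughout, for both
  trimming directions.
* Exact brute-force kNN within clusters (clusters are small); the kd-tree
  search used is exact and is verified against the full pairwise distance
  matrix in the tests.
* Alpha-hull boundary edges are found among Delaunay edges only (every
  boundary edge is Delaunay), with an empty-disc tolerance of
  $10^{-9}\,$`hull_alpha`; arcs are approximated by chords for distance
  queries.
* The CLR geometric-mean term uses all genes of the cell including zeros
  (`log1p` form), so an all-zero cell maps to zeros rather than an error.
* MTX files follow the CellRanger dialect: genes as rows, 1-based indices
  on disk, duplicate gene symbols made unique on read.
* Breakdown levels must start at 0 so that retention has its fixed
  baseline; clusters with no baseline markers report `NA` retention.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
deliberately modest sizes — oracle checks on clusters of 5–60 cells and
2–50 features, planted datasets of 300 cells × 500 genes, clouds of 1000
cells, 200-replicate null calibrations — sizes at which every oracle
(brute-force distances, exhaustive rank-sum enumeration, dense boundary
sampling) is itself cheap to compute.

## Limitations

Trimming small clusters costs statistical power and can inflate false
negatives; the quantile rule always flags a fixed fraction when $\alpha >
0$, whether or not genuine outliers exist; the 2-D hull variant inherits
the distortions of the embedding it reads; and different outlier
definitions will flag different cells — the robustness statistics remain
interpretable because they compare marker sets, not outlier sets.
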