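---
title: "Methods: spatial domain identification by embedded clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial domain identification by embedded clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spadec)
```

This vignette is the package's own account of its models and the design
decisions behind them. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The problem and the data model

Spot-based spatial transcriptomics assigns an expression vector over
thousands of genes to each capture location ("spot") on a regular array.
A Visium array is a hexagonal lattice, so each interior spot has six
equidistant physical neighbors; the package's spatial defaults follow
from that geometry. The goal is a partition of the spots into spatial
domains: regions that are transcriptionally coherent *and* spatially
contiguous. Everything operates on a `spatial_dataset`: a non-negative
spot-by-gene matrix, a two-column planar coordinate table, unique spot
and gene identifiers, optional truth labels (evaluation only), and
optional extra feature blocks such as precomputed image embeddings.
Spots, not cells, are the unit throughout: a spot aggregates one to
several cells, which is why boundary spots naturally show hybrid
expression and why spatial refinement is useful at all.

## Gene filtration

**Scatter filtration** suppresses ubiquitously top-expressed genes.
Per iteration it samples `m` spots without replacement, collects each
sampled spot's top-`L` expressed genes, scores every retained gene by
its occurrence count across the sample, and removes the
`r = floor(knob / 10)` highest-scoring genes. Genes that sit in the top
of nearly every spot's expression profile are dominated by housekeeping
and general-viability programs; removing them raises the relative weight
of spatially localized signals. Defaults: `knob = 100` (10 genes per
iteration), `T = 10` iterations, `m = max(50, 10%` of spots`)`,
`L = 50`. `T`, `m` and `L` are the package's own choices (exposed in
`filtration_config()`); sampling is without replacement. Occurrence-score
ties at the removal boundary are broken by higher total expression, then
by gene index, so a seeded run is fully deterministic.

**HVG selection** ranks genes by variance-stabilized standardized
variance: a loess trend (degree 2, span 0.3) of log10 variance against
log10 mean predicts each gene's expected standard deviation;
standardized counts are clipped at `sqrt(n)`; the variance of the
clipped values is the ranking score. Zero-variance genes rank last.

**Order of operations.** The `Scatter` and `FACT` variants apply
scatter filtration first, then HVG selection; `G`/`GS`/`GN`/`ACT` apply
HVG selection only.

## Normalization

Four steps, in order: per-spot library-size scaling to
`target_sum = 1e4`; `log1p`; per-gene z-scoring (zero-variance genes map
to exactly 0); clipping to `[-10, 10]`. The clip interval is a package
default — wide enough that clipping only touches genuine outliers of the
z-scored distribution. The z-score mean/sd are per gene (column-wise),
the standard scaling convention; a global-scalar mode exists behind
`mean_mode = "global"` for completeness. A spot with zero total count is
an error naming the spot, since library-size scaling is undefined there.

## Representation learning

The autoencoder is **purely linear and bias-free**, exactly as the model
equations are written: `Z = X W1`, `X̂ = Z W2`, clustering scores
`S = Z W3` with a row-softmax. One practical consequence, demonstrated
in the test suite: a bias-free linear clustering layer cannot separate
classes whose score difference never changes sign along any direction
(e.g. collinear class centers through the origin).

Training choices the source equations leave open, fixed as follows:

* **Optimizer**: full-batch Adam, learning rate `1e-3`. Datasets at the
  spot counts this package targets fit comfortably in memory, so
  mini-batching would add noise for no benefit.
* **Epochs**: 200 / 100 / 200 for the reconstruction, alignment and
  joint stages.
* **Loss weights**: `lambda_rec = 1`, `lambda_clust = 0.1`.
* **KL averaging**: the clustering loss is the *mean* over spots of the
  row-wise KL divergence, not the grand total, so `lambda_clust` has
  the same meaning regardless of `n`. This is a documented divergence
  from a literal total-sum reading of the divergence formula.
* **Numerical floors**: `Q` is floored at `1e-10` before any logarithm;
  the softmax subtracts the row maximum before exponentiation.
* **Target refresh**: one-hot targets are rebuilt from a fresh mixture
  fit plus spatial refinement once before stage 2 and once before
  stage 3 — not every epoch. The staged design deliberately separates
  representation formation from cluster refinement; refreshing every
  epoch would re-couple them.

The hill-climbing trainer (`hill_climb_train()`) is retained purely as
an ablation: Gaussian perturbations of one weight tensor per step
(round-robin, scale 0.01), accepted iff the silhouette of a
density-based clustering of `Z` strictly improves, with degenerate
single-cluster solutions scored −1. It is not part of any variant's
final path.

## Mixture labeling and spatial refinement

Final labels come from a Gaussian mixture fitted to `Z` by EM, restarted
from `n_init = 5` k-means seedings, best log-likelihood wins,
convergence at a log-likelihood change below `1e-6`, covariance
diagonals ridged by `1e-6`. The default covariance family is a **single
full covariance shared by all components** — the closest simple analogue
of the equal-covariance mixture families used by model-based clustering
packages, and the family under which the fit is equivariant to the
invertible linear distortions a trained `W1` can impose on the latent
basis. Per-component full and diagonal families are configurable. Empty
components are reported via `n_effective_clusters`, never silently
re-fitted: asking for 7 domains and reliably finding 6 is a result, not
an error.

Refinement is a **single synchronous pass** by default: every spot is
judged against the pre-pass labels of its `k = 6` spatial nearest
neighbors and flips only to a label held by strictly more than `k/2` of
them; ties and non-strict majorities leave the spot unchanged. An
iterate-to-fixed-point mode (capped at 10 passes) is available. The
refined mixture labels both seed the stage-2/3 targets and form the
final output.

## Quality metrics

Supervised: ARI and NMI from the contingency table (natural logarithms;
NMI of two zero-entropy labelings is defined as 1), homogeneity and
completeness from conditional entropies. Unsupervised: average
silhouette width (Euclidean, singletons contribute 0), PAS, CHAOS, and
Moran's I / Geary's C on per-cluster one-hot indicators with
row-normalized kNN weights, reported as cluster-size-weighted means.

The PAS and CHAOS parameterizations are package decisions, stated
prominently because the literature varies: PAS is the fraction of spots
whose label differs from at least 6 of their 10 nearest spatial
neighbors; CHAOS is the spot-count-weighted mean, across clusters, of
the mean within-cluster 1-nearest-neighbor edge length on z-scored
coordinates. Both knobs are exposed. One consequence of the 10-neighbor
rule worth knowing: a checkerboard labeling on a square lattice is *not*
maximally abnormal (its 10-neighborhood contains 4 same-parity diagonal
and 2 same-parity distance-2 spots); single-row stripes are.

For cross-method comparison the silhouette is computed on a **shared
feature space** — the leading 20 principal components of the normalized
expression matrix — so that candidate labelings from external tools are
scored on identical features rather than each tool's own embedding.

## Ensemble selection

For each slide, the five metrics are min-max normalized across the
candidate set with an `epsilon = 1e-8` denominator guard; PAS, CHAOS and
Geary's C are flipped to benefit form. The balanced rule selects the
candidate minimizing squared Euclidean distance to the reference profile
(max ASW, max Moran's I, medians of the rest; even candidate counts use
the midpoint of the central pair). Distance and single-metric ties break
lexicographically by candidate name, with a warning. The selector's
interface deliberately has no truth-label parameter: selection is
unsupervised by construction, and agreement metrics are computed only
afterwards, outside the selector.

## Benchmark statistics

The Friedman test ranks methods within each slide (average ranks on
ties) and applies the standard tie correction by default. The paired
Wilcoxon test is one-sided and **exact**: the null distribution of the
positive rank sum is built over all `2^n` sign patterns (via a
generating-function convolution, identical to full enumeration), with
zero differences dropped and tied absolute differences given average
ranks. Exactness matters: twelve concordant slides give
`p = 1/4096 ≈ 2.44e-4`, and with four baseline comparisons Holm's
step-down turns that into `9.77e-4` — values a normal approximation
cannot hit. One boundary convention to note: the exact p-value is
`P(W+ >= observed)`, so two differences of equal magnitude and opposite
sign give `p = 0.75`, not `0.5` (a mid-p convention would give 0.5; the
package does not use one). Rank-biserial effect size is
`(W+ − W−)/(W+ + W−)`.

When reproducing a published multi-method comparison, which rows enter
the Friedman test matters: the packaged 13-row benchmark table yields
χ² = 69.7 over all rows but χ² = 55.26 over the ten rows that exclude
the three single-metric ensemble sensitivity variants, and the latter is
what `scripts/acceptance.R` computes (via the `friedman_methods`
argument). The single-metric variants share most of their labels with
the balanced ensemble, so including them inflates concordance.

## The synthetic generator: what it emulates and what it does not

`simulate_tissue()` produces a hexagonal offset lattice (odd rows
shifted by half a spot, row spacing √3/2, so Euclidean 6-NN reproduces
Visium adjacency), laminar domains stacked along y with optional
sine-warped boundaries, and negative-binomial counts
(`size = 2`, clearly overdispersed, as spot-level UMI data are) scaled
by a log-normal per-spot depth factor (`sigma = 0.3`).

Gene programs: per-gene baseline means are log-normal around
`baseline_mean = 5` (sigma = 1 in log2). This spread is essential
realism, not decoration — with a flat baseline, the HVG mean–variance
trend passes through the marker stratum (the markers are then the only
genes at their mean, so their variance *is* the trend) and
variance-stabilized selection is structurally blind to them, an artifact
no real transcriptome exhibits. Markers get `2^2 = 4`-fold elevated
means inside their domain; housekeeping genes sit at `10 ×
baseline_mean` everywhere, which places them in the top-50 expression
set of ≳90% of spots and makes scatter filtration testable. Defaults: a
30 × 30 lattice, 4 domains, 200 genes, 10 markers per domain, 20
housekeeping genes.

What the generator does **not** emulate: dropout beyond what the
negative binomial implies, gene–gene correlation within programs,
gradual domain boundaries or partial-volume mixing, platform artifacts
(spot swapping, section folds), or image modalities. A green end-to-end
test therefore establishes that the pipeline recovers clean laminar
structure at a realistic noise level — not that it matches annotation
quality on real cortex, where boundaries are gradual and labels
themselves are imperfect.

## Degenerate inputs and determinism

All randomness flows from one integer seed, expanded into named
per-stage substreams (filtration, each mixture fit, initialization), so
identical inputs and configuration reproduce labels bit-for-bit — a
property the acceptance suite checks by running the full pipeline twice.
Deliberate error cases: `h5ad` input (no HDF5 reader in this build),
zero barcode overlap, duplicated identifiers, zero-total spots,
exhausting the gene set in filtration, silhouette of a single cluster,
spatial autocorrelation of a constant labeling, and a Wilcoxon test with
all-zero differences. Model checkpoints are plain JSON.

## Known limitations

* The encoder is a single linear layer; tissues whose domain structure
  is only non-linearly separable in expression space are out of reach
  by design (the nonlinear-variant flag is off by default and untested
  at scale).
* The location-selection ranking (total count as an informativeness
  proxy) is a simple heuristic; `rank_fun` allows alternatives.
* `K` is user-supplied; the package deliberately does not select it.
* Exact kNN and silhouette computations are quadratic in spot count —
  fine for array-based sections (thousands of spots), not tuned for
  bead-based assays with 10^5 locations; subsample first
  (`select_locations()`).
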