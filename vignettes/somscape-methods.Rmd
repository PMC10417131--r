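---
title: "Methods: SOM portrayal of transcriptome landscapes"
author: "somscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SOM portrayal of transcriptome landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`somscape` analyses bulk tumor transcriptomes by *portrayal*: the
expression profile of every gene (its vector of centralized
log10-expression values across all samples) is treated as a point in
sample space and clustered onto a two-dimensional grid by a
self-organizing map (SOM). Each grid unit ("metagene") carries a
prototype profile; the image formed by evaluating all metagenes in one
sample is that sample's *portrait*. Co-expressed gene modules appear as
spot-like regions, and all downstream analyses — spot modules, gene-set
scores, trajectories, prognostic maps — operate on this reduced
landscape instead of the raw gene-level matrix.

This vignette documents the model, the tunable parameters and their
defaults, the numerical conventions, what the synthetic-cohort generator
does and does not emulate, and the design decisions taken where several
reasonable options existed.

# Preprocessing

The pipeline assumes centralized log10 expression:

1. `log10Transform(x, offset)` — elementwise `log10(x + offset)`. The
   offset defaults to 0 and must make all values positive; the error
   message names the offending gene and sample.
2. `quantileNormalize(x)` — classical quantile normalization across
   samples (via `limma::normalizeQuantiles`): after normalization every
   column's sorted values equal the cross-column rank means. Ties within
   a column receive the mean of the reference values at their tied
   ranks.
3. `centralize(x)` — subtracts each gene's mean across samples, so
   positive values read as over-expression and negative as
   under-expression relative to the cohort average. Centralization is
   idempotent.

Repository data usually arrive already normalized; `preprocessExpression()`
therefore exposes skip flags for steps 1–2. Missing values are rejected
at read time rather than imputed.

# SOM training

`trainSOM()` implements classic *batch* SOM training on a planar
(non-toroidal) rectangular grid, default 50 × 50 = 2500 metagenes:

* **Initialization.** Prototypes are laid out linearly on the plane
  spanned by the first two principal components of the gene cloud,
  scaled to ±2 SD of the respective scores. This makes training close to
  deterministic and independent of gene order.
* **Batch sweep.** Every gene is assigned to its best-matching unit
  (BMU; Euclidean distance; ties go to the lowest linear pixel index),
  then every prototype is replaced by the Gaussian-neighborhood-weighted
  mean of all gene profiles. The Gaussian kernel factorizes over the
  column and row coordinates, so the smoothing runs as two small 1-D
  kernel products.
* **Annealing.** The neighborhood radius decreases linearly from half
  the grid width to 1 over the sweeps (default 30 epochs).
* **Quantization error (QE).** The mean distance of genes to their BMU
  is traced per epoch. Note that under PCA initialization the first
  large-radius sweeps *flatten* the map and can raise QE before the
  shrinking neighborhood lets it decrease; the trace is monotonically
  non-increasing over the later epochs and ends below its starting
  value, which is what the tests assert.

Pixels are addressed as `(col, row)`, 0-based, origin top-left, with
row-major linear index `row * width + col`. All maps and portraits are
stored as vectors in this order; `portraitMatrix()` reshapes for
display.

# Spot modules

Overexpression spots are detected on a summary map — either the
pixelwise maximum over group mean portraits, or the per-pixel 90%
quantile over individual portraits (the "personalized" summary, which
surfaces patterns independent of any grouping).

`detectSpots()` thresholds the map at a per-map percentile (default
0.82) and segments the surviving relief by grayscale watershed
(`EBImage::watershed`, 8-connectivity). The watershed `tolerance`
(default 0.1, in centralized log10 units) is the minimum height of a
local peak above its saddle to count as a separate spot; `tolerance =
Inf` reduces the rule to plain connected-component labeling. The
watershed step matters because neighboring modules routinely touch above
any single threshold that is low enough to cover weak modules: a plain
component rule then either merges adjacent spots or misses faint ones,
whereas the watershed splits touching blobs at their saddle. Components
smaller than `minPixels` (default 4) are dropped, and spots are labeled
A, B, … by descending peak height — the labels are positional within one
run and carry no meaning across datasets.

A spot's gene list is the set of genes whose BMU lies in its pixel set;
its per-sample expression profile is the mean prototype value over the
pixel set. Downstream spot statistics:

* `spotAUC()` — one-vs-rest classification power as the Mann–Whitney
  AUC (mid-ranks for ties). Values below 0.5 are reported as-is: they
  indicate that *under*-expression of the spot marks the subtype.
* `ternaryCoordinates()` — negative values clipped to 0, then
  normalized to sum 1; an all-zero triple maps to the centroid.
* `wtoMatrix()` — signed weighted topological overlap between spot
  profiles, `w_ij = (Σ_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 −
  |a_ij|)` with signed adjacency `a` the Pearson correlation and
  connectivity `k_i = Σ_{k≠i} |a_ik|`. The signed variant is used
  because anticorrelation between spots is itself a finding of interest.
* `contaminationSplit()` — two-group split of a single spot profile by
  complete-linkage hierarchical clustering cut at 2; "high" is the
  cluster with the larger mean. With more than two latent levels (clean,
  contaminated, tissue-like) the 2-cut lands at the widest gap, which
  need not be the clean/contaminated boundary; the function is exact for
  genuinely bimodal profiles.

# Gene-set scores

The gene set Z score of set *S* in sample *s* is

```
GSZ(S, s) = (mean_{g∈S} x_gs − mean_g x_gs) / (sd_g(x_gs) / sqrt(|S|))
```

with `|S|` counting only set genes present in the matrix. This
standardized-mean form is adopted as the package's definition; it is
exactly zero when the set contains all genes and reduces to a single
gene's within-sample z-score for singletons — two invariants any
refinement must preserve. `setDensityMap()` counts set genes per pixel
(sums to the matchable set size), and `spotOverrepresentation()` tests
spot/set overlaps with the one-sided hypergeometric tail,
Benjamini–Hochberg-corrected across the collection. The reported tail
p-value is discrete and therefore conservative (super-uniform) under the
null; the test suite checks exact uniformity after de-randomizing the
point mass.

# Trajectory

Published portrayal analyses typically run a third-party principal-graph
tool for this stage. `somscape` deliberately substitutes a fully
specified pipeline — PCA to `nComponents` (default 10), k-means with `nNodes`
centroids (default 20), minimum spanning tree over the centroids with
Euclidean weights, nearest-node sample projection — because the tool's
internals are not part of this package's contract and exact replication
is out of scope. Consequences to keep in mind:

* Segments are maximal branch-free node paths (split at nodes of degree
  ≥ 3), labeled `Seg1, Seg2, …` by descending sample count. A flat
  decomposition is used; nested sub-segment numbering is presentation,
  not algorithm.
* Pseudotime is the geodesic distance from a root node along the tree.
  The root is an explicit node or the leaf whose projected samples
  maximize a named spot's mean expression — root choice is a scientific
  input, not an inference.
* Node density controls spurious branching: with roughly one node per
  twelve samples the tree of a planted one-dimensional gradient is
  reliably a simple path; at much higher node densities noise
  dimensions sprout short side branches. The gradient-recovery tests
  use 8 nodes and 3 components for 100 samples for this reason.
* k-means is run with 5 deterministic-seeded starts
  (Hartigan–Wong, `stats::kmeans`); empty clusters are handled by the
  base implementation.

# Prognostic maps and the risk score

For each pixel, samples split into a high-expression group (centralized
metagene expression > 0, or > +1 within-pixel SD under `gt-1sd`) and the
rest; the hazard ratio is `exp(β)` from a univariate Cox
proportional-hazards fit of the indicator (Efron ties, via
`survival::coxph.fit`). "One standard deviation" is read as the
pixel-wise SD across samples; a global-SD reading is the obvious
alternative and the mode is a flag. Pixels with fewer than `minGroup`
(default 5) samples in either arm, or non-convergent fits, are masked.
The univariate-Cox operationalization is a choice: the source analyses
only state that a hazard ratio is computed per metagene.

`extremeMetagenes()` selects the maximum- and minimum-HR pixels. Because
neighboring prototypes are near-copies, per-pixel estimates are
spatially coherent while their estimation noise is not; the log-HR map
is therefore smoothed with a small Gaussian kernel (σ = 1.5 px,
normalized convolution that ignores masked pixels) before the
argmax/argmin, so blob-level extremes beat isolated noise pixels.
`smoothRadius = 0` restores raw per-pixel selection. Ties resolve to the
lower linear index. If an extreme pixel hosts fewer than `minGenes`
(default 20) genes, the list is padded from growing 8-neighbor rings,
stopping exactly at the requested count (within a ring, pixels are taken
in linear-index order).

The per-sample score is the mean expression over the maxHR gene list
minus the mean over the minHR list — higher means worse predicted
prognosis; swapping the lists negates the score exactly. A spot-based
variant substitutes two spot gene lists. `splitRiskGroups()` takes the
top and bottom `percentile`% (ties broken by sample ID), estimates
Kaplan–Meier curves per group and reports the two-group log-rank test.
`patientHeterogeneity()` summarizes the score per patient (mean, sample
SD over lesions; SD undefined for singletons) and compares the range of
patient means with the mean within-patient SD.

# The synthetic-cohort generator

`generateCohort()` produces ground-truth cohorts with the statistical
structure the pipeline assumes. The generative model, on the
centralized log10 scale:

* Patients draw a lesion count (default P(1)=0.7, P(2)=0.2, P(3)=0.1)
  and a subtype; all lesions of a patient share the subtype.
* Each patient draws per-module activations: the subtype's design level
  plus Gaussian jitter (`activationSd`, default 0.25) — biological
  variability of module activity, shared by the patient's lesions.
* Module genes carry their module's activation; background genes sit at
  0. Per-gene Gaussian noise is added at the patient level
  (`noiseSd`, default 0.4) and per lesion (`intraPatientSd`, default
  0.045 — about 10% of the typical inter-sample SD of
  `sqrt(noiseSd² + activationSd²) ≈ 0.45`).
* A contamination flag (default 35% of samples, across all subtypes)
  adds `contaminationLevel` (default 1.0) to the liver-like module's
  activation of that sample.
* Survival times are exponential with rate `exp(Σ β_m a_m)`; censoring
  is an independent per-sample exponential calibrated so each sample is
  censored with probability `censorFraction` (default 0.2).

The default design (`defaultCohortDesign()`): 6000 genes, 120 samples,
six modules A–F of 200–400 genes, five tumor subtypes S1–S5 (18% each)
plus a liver-like group LIV (10%). Each subtype has one dominant
overexpression module (A→S1, B→S2, D→S3, C→S4, E→S5); the
epithelial-like module A is under-expressed (−0.8) and the cycling-like
module C mildly under-expressed (−0.4) in the mesenchymal-like S5;
module F is the liver signature (+1.5 in LIV, plus contamination). The
default survival model puts β = +0.7 on module A, so the risk axis runs
between the S1-like (high A, inferior prognosis) and S5-like (low A,
favorable) ends of the landscape. C's under-expression in S5 is kept
mild deliberately: were it as strong as A's, the hazard planted on A
would induce an almost equally strong association in the C region, and
"which module carries the risk" would be ill-defined in the ground
truth itself. No quantitative noise or effect sizes are available from
the motivating study, so these defaults are calibrated once to make the
planted structure recoverable with margin, and are not revisited.

What the generator does **not** emulate: probe-level microarray signal,
batch effects, copy-number dosage, single-cell data, non-proportional
hazards, or correlated gene-gene noise within modules beyond the shared
activation. Passing tests on this generator therefore demonstrate that
the pipeline recovers the structure it assumes — not that real cohorts
satisfy those assumptions.

# Numerical conventions and test design

* Determinism: every stochastic step takes a seed; identical seeds give
  bit-identical cohorts, maps and trees.
* BMU ties, HR-extreme ties and risk-split score ties all resolve by
  the lowest index / sample ID, so results are order-stable.
* Degenerate inputs: constant spot profiles are an error in `wtoMatrix`
  (undefined correlation) and a warned all-low split in
  `contaminationSplit`; single-cluster silhouettes are an error;
  all-censored cohorts are an error.
* The permutation-null check of the AUC uses balanced groups at
  n = 200: the permutation SD of the AUC is `sqrt((n+1)/(12 n₁ n₂))`,
  and only balanced groups make a ±0.1 band a ~2 SD statement at this
  sample size.
* Problem sizes in the test-suite: full-resolution (50 × 50) maps are
  trained on 6000 × 120 and 6000 × 200 cohorts (five and one seeds
  respectively); gradient-recovery uses ten 2000 × 100 cohorts on
  20 × 20 maps; survival simulations redraw outcomes on a fixed trained
  map (50 draws for power, 20 for null calibration). These sizes keep
  the planted effects comfortably detectable while the whole suite runs
  in minutes.

# Known limitations

* The SOM is planar and rectangular only; no toroidal, growing or
  hierarchical variants.
* Spot labels are positional; no cross-dataset matching of spot
  identities is attempted.
* The watershed tolerance is an absolute height in map units, so maps
  on very different scales need a rescaled tolerance.
* The principal tree is a deliberate simplification; its segment
  structure should be read as a coarse ordering device, not as a
  validated developmental inference.
* Hazard-ratio maps use univariate fits per pixel with no adjustment
  for clinical covariates or multiple testing; they are exploratory
  visualizations from which the two extreme metagenes are taken.
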