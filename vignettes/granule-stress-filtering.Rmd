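---
title: "Granule-based stress filtering: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granule-based stress filtering: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science behind
`granufi()`: the model and its assumptions, the parameters that matter, the
numerical choices made where several readings were defensible, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## The model

The object being estimated is a per-gene-set **upper threshold** separating
a non-stressed bulk of cells from a stressed upper tail, under four
assumptions:

* (a) granules pool enough cells that granule-averaged scores are
  approximately Gaussian for the non-stressed population (central limit
  theorem over member cells);
* (b) non-stressed scores are draws from one common distribution;
* (c) stressed scores are substantially higher than non-stressed ones;
* (d) stressed cells are the minority.

Under (c) and (d) the **median** of granule scores estimates the Gaussian
location `m` untouched by the stressed tail, and the dispersion can be
estimated from the lower half alone: the scale `s` is the root-mean-square
deviation about `m` of the scores strictly below `m`. The threshold is the
theoretical `q`-quantile of the fitted Gaussian, `t = m + qnorm(q) * s`,
with `q = 0.99` by default. For a symmetric null this lower-tail RMS
converges to the true standard deviation, so on uncontaminated standard
normal scores `t -> qnorm(0.99)` and 99% of granules fall below it — the
calibration that `scripts/acceptance.R` and the test suite verify by Monte
Carlo.

Assumption (a) is enforced upstream: a resolution search targets a median
granule size of 100–200 cells and granules under 30 cells are dissolved.

### Scale estimator

Two estimators were candidates for `s`: the sample SD of the lower half
about its own mean, and the RMS about the median. The Gaussian-fit framing
makes the RMS the faithful choice — the lower half of a Gaussian centred at
`m` has RMS deviation about `m` equal to the full distribution's SD, while
the lower half's own SD is biased low and would need a half-normal
correction factor. The divisor is the count of scores below the median
(population form); with all scores equal, `s = 0` and `t = m`, so a
constant score column produces zero stressed granules.

### Combination rule

Positive-direction scores (glycolysis, ER stress) are OR-combined: one
exceedance marks the granule stressed. Negative-direction scores
(neuro-/gliogenesis) are OR-combined and veto the call: cell types with
natively high stress-adjacent programs (for example choroid plexus, which
scores high on glycolysis) are protected by giving their lineage program as
a negative set. Exceedance is **strict** (`score > t`); granules exactly at
the threshold are non-stressed, the conservative reading. The same
upper-tail construction is used for negative scores; a two-sided variant
was considered and rejected because the veto is only meaningful for
granules unusually *high* in the lineage score.

## Pipeline parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_genes` | 500 | genes/cell | standard droplet QC floor |
| `max_mito` | 0.20 | fraction | dying-cell indicator |
| `max_ribo` | 0.30 | fraction | low-complexity libraries |
| `n_hvg` | 2000 | genes | conventional HVG count |
| `n_pcs` | 50 | components | conventional PC depth |
| `knn_k` | 20 | neighbors | upstream-ecosystem default |
| `snn_prune` | 1/15 | Jaccard | upstream-ecosystem default |
| `lower_median`, `upper_median` | 100, 200 | cells | granule CLT vs. resolution trade-off |
| `min_granule` | 30 | cells | minimum for a stable mean |
| `q` | 0.99 | quantile | 1% false-positive budget per score under the null |
| `n_bins` | 25 | bins | expression-matched control granularity |
| `n_ctrl` | 100 | genes/target | control-pool variance reduction |

`knn_k` and `snn_prune` have no principled closed form; the values mirror
the defaults of the ecosystem this pipeline interoperates with, and both
are exposed in `run_config()`. Smaller datasets warrant smaller granule
bounds (e.g. 75–150); the bounds are first-class config, not constants.

## Numerical choices

* **Binning** is equal-frequency over the *rank* of per-gene mean
  expression, ties broken by symbol order. Rank-based binning makes module
  scores invariant to adding a constant to the whole matrix (a property the
  tests assert) and is robust to the heavy right tail of mean expression.
* **Control sampling** is uniform without replacement within a bin (with
  replacement only when a bin is smaller than `n_ctrl`), the draws of all
  target genes are pooled into one deduplicated control set, and target
  genes are excluded from the candidate pool so a set cannot partially
  cancel itself.
* **Resolution search**: geometric doubling/halving from resolution 1
  until the 100–200 median interval is bracketed, then bisection, capped at
  30 clustering calls; the interval is closed, so a median of exactly 100
  or 200 is accepted. The same seed is reused for every clustering call so
  the returned resolution reproduces its partition.
* **Reassignment** is single-pass with recipient centroids frozen before
  any transfer. Recipients are restricted to granules already at or above
  `min_granule`, which guarantees termination and the minimum-size
  post-condition in one pass; an iterated variant (recompute centroids
  after each move) was considered and rejected as it may oscillate and
  changes results only marginally on well-separated embeddings. Nearest is
  by Euclidean distance in 3-D UMAP space; the 3-D embedding is computed
  unconditionally for this purpose, 2-D only for plotting.
* **Degenerate inputs**: all-zero cells normalize to zero rows with a
  warning; zero-variance genes rank last in HVG selection and are dropped
  before PCA scaling; a gene set retaining fewer than `min_set_size = 5`
  detected genes is a hard error naming the set.
* **Seeds**: one user-facing seed fans out to per-stage seeds derived by
  hashing the stage name, so each stage is independently reproducible and
  re-running one stage does not perturb another's stream.

## The synthetic-data generator

`synth_generate()` draws counts from a negative binomial (gene-level
dispersion 0.3) with log-normal library sizes and log-normal base rates.
Four cell programs each elevate a disjoint 50-gene marker set; a stressed
state is overlaid on cells of *every* program (stress is a state, not a
type): two disjoint 50-gene stress sets are multiplied by
`exp(stress_lfc)` and all lineage marker sets by
`exp(-lineage_depletion_lfc)`. The default fixture uses 20,000 cells,
2,000 genes, a planted stressed fraction of 0.15 — near commonly observed
organoid stressed fractions — and `stress_lfc = 1.5`.

The generator emulates the features the method relies on: overdispersed
counts, depth variation, multiple overlapping identities with a shared
stress signature, and stressed cells that co-embed across programs. It does
**not** emulate batch effects, ambient RNA, doublets, trajectory structure,
or mitochondrial/ribosomal content (QC passes nearly all synthetic cells).
Passing tests therefore demonstrate the method's contract — calibration,
granule-size control, planted-population recovery — not its behaviour under
real-data artifacts, which is why every threshold remains inspectable and
overridable (`manual_thresholds`, `cmd_threshold_report()`).

## Problem sizes used by the tests

The test suite exercises the full pipeline at 20,000 cells once (the
canonical fixture) and uses 500–2,500-cell simulations for unit-level
pipeline properties; oracle-equivalence checks run on 20 × 60 matrices
where brute force is exact. These sizes make the whole suite complete in a
few minutes while keeping every contract at the scale it is stated for.

## Limitations

* The threshold model assumes a unimodal non-stressed bulk per score; a
  dataset whose non-stressed population is itself strongly bimodal in a
  score violates assumption (b) and can push `m` off-centre. Inspect with
  `plot()` or `cmd_threshold_report()` and override if needed.
* Louvain granule boundaries are not stress-aware: cells of a thinly
  spread stressed population that co-cluster with non-stressed cells are
  diluted below threshold. The single-cell mode trades this dilution for
  substantially more noise (lower specificity at matched call counts — a
  property the tests assert).
* Scores are computed on the log-normalized matrix; pathological
  composition shifts (one program dominating the library) move all scores
  jointly and are only partially cancelled by the binned controls.
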