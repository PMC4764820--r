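---
title: "Detecting Y-chromosome microdeletions from STS capture depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Y-chromosome microdeletions from STS capture depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ycmscan)
```

## The problem and the model

Y-chromosomal microdeletions (YCMs) are a major genetic cause of
non-obstructive azoospermia (NOA). The male-specific Y (MSY) is packed
with near-identical amplicons and palindromes that defeat unique short-read
mapping, so whole-genome approaches discard exactly the regions (AZFa,
AZFb, AZFc) where deletions matter. Sequence-tagged sites (STSs) — short,
uniquely identifiable landmarks with known primers — sidestep this: if a
panel of ~2000 STSs across the MSY is captured and sequenced, the mean
read depth over each STS tracks its copy state. A deleted STS does not
drop to zero depth (non-specific capture, sequencing and misalignment
leave a residual), but it drops far below the depth the same STS shows in
intact samples.

`ycmscan` turns a samples x STSs matrix of mean depths `D[i, j]` into
per-pair deletion calls and cohort-level statistics, in five stages:

1. **QC cascade** (`run_qc()`): remove outlier samples and STSs (Tukey
   fences at `1.5 x IQR` on mean depths, both removals computed on the
   initial matrix and applied jointly), remove STSs whose raw median
   depth is below 15x (an STS can only reveal a deletion if it is
   captured deeply when intact), divide each sample's row by its mean
   (after which row means are exactly 1), then drop samples whose
   normalized-depth standard deviation exceeds 0.7.
2. **Predictors** (`compute_features()`): for each qualified pair,
   * `f1 = log(phi(z))`, `z = (D[i,j] - mu_j) / sigma_j` — the
     log-density of the depth under the STS's normal approximation across
     samples;
   * `f2 = D[i,j] / RMD_j` — depth over the STS's median depth across
     samples;
   * `f3 = D[i,j] / SMD_i` — depth over the sample's median depth across
     STSs.
3. **Classification** (`train_classifier()`, `classify()`): a soft-margin
   SVM with Gaussian kernel `K(x, y) = exp(-||x - y||^2 / (2 sigma^2))`
   trained on a small set of validated (sample, STS) events, with `C` and
   `sigma` selected by repeated stratified 4-fold cross-validation over
   the grid `2^-5 .. 2^15` (`grid_search_cv()`). The shipped operating
   point is `C = 2^9`, `sigma = 2^3`.
4. **Merging** (`merge_calls()`): consecutive deleted STSs under 100 kb
   apart are connected into deletion intervals; a non-deleted multi-copy
   STS between them is skipped (it can lose copies without a depth
   dropout), a non-deleted single-copy STS always breaks the run.
5. **Cohort statistics**: per-group summaries (`summarize_groups()`),
   chi-square / Kruskal-Wallis contrasts (`compare_groups()`), one-sided
   Fisher haplogroup association (`haplogroup_association()`), deletion
   enrichment per haplogroup (`haplogroup_deletion_enrichment()`), and
   annotation-category enrichment (`annotation_enrichment()`).

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `iqr_multiplier` | – | 1.5 | standard Tukey fence; screens capture failures |
| `median_depth_cutoff` | reads | 15 | below this, an intact STS is not reliably distinguishable from a deleted one; the value is a published operating point |
| `sd_cutoff` | – | 0.7 | samples with more dispersed normalized depth reflect failed experiments |
| `C`, `sigma` | – | `2^9`, `2^3` | grid-search selection on validated training data |
| `max_gap` | bp | 100 000 | above the 95th percentile (~50 kb) of inter-probe distances, balancing split vs spurious joins |

Boundary semantics are deliberately explicit: the median cutoff removes
at `median < 15` (an STS at exactly 15 stays), the SD filter removes at
`sd > 0.7` (a sample at exactly 0.7 stays), quantiles use linear
interpolation between order statistics (R type 7), and standard
deviations use the n−1 denominator. The gap between two STSs is
`start(downstream) − end(upstream)` in 0-based half-open (BED)
coordinates.

## Numerical and design choices

* **"Probability" in f1.** The source formulation scales depth to zero
  mean and unit variance and takes "the logarithm of the probability"
  under the normal approximation. The direct reading — the log *density*
  of the z-score, `f1 = -log(2*pi)/2 - z^2/2` — is the default; the
  lower-tail log-CDF alternative is available via
  `compute_features(..., f1_mode = "tail")`. The two differ in that the
  density penalizes both tails; the classifier's other two predictors
  disambiguate low from high depth.
* **RMD/SMD on normalized depths.** All three predictors are computed on
  the normalized matrix, so per-sample data-production variation is
  divided out once, upstream. Scaling raw rows by constants provably
  leaves all features unchanged (tested).
* **Degenerate STSs** (`sigma_j = 0`) are excluded from the feature
  matrix with a warning and appear as `not_evaluated` in the call matrix;
  no variance floor is applied, because a zero-variance column carries no
  classification signal.
* **Kernel parameterization.** `sigma` is a *bandwidth*:
  `K = exp(-d^2 / (2 sigma^2))`. Implementations using the gamma
  convention must set `gamma = 1 / (2 sigma^2)`. Features are not
  rescaled before the SVM — the three predictors are already on
  comparable scales by construction, and rescaling would silently change
  the meaning of `sigma`.
* **CV concordance** is plain held-out accuracy, folds are stratified by
  class, and grid ties break to the smallest `C`, then the smallest
  `sigma` (prefer the least complex boundary, deterministically). At
  134 training events, concordances tie heavily across the grid —
  dozens of cells can share the maximum — so stability comparisons
  between repetition counts are made on distinct concordance values,
  not raw cell ranks.
* **Merging consults only evaluated STSs.** A QC-removed or degenerate
  STS carries no deletion evidence either way, so it neither joins nor
  breaks a run. Outer interval bounds come from the nearest flanking
  *called non-deleted* STS, clamped to `inner +/- max_gap`; recurrent
  merged deletions are keyed by exact member-STS set.
* **Re-running QC on its own output.** The IQR and median-depth stages
  are defined on raw depths; on a normalized matrix `run_qc()` applies
  only the SD filter (and normalization is the identity), which makes
  the cascade idempotent. Re-applying Tukey fences to their own
  truncated output would keep flagging new borderline values — a known
  property of iterated IQR trimming, not a data pathology.
* **Tests without Yates correction.** The chi-square tests use the plain
  Pearson statistic (`correct = FALSE`, switchable). The published
  headline p-values are not exactly recoverable under either convention,
  so the uncorrected statistic — which matches the textbook formula the
  test suite checks by explicit summation — is the documented default.
* **One-sided Fisher direction.** Each haplogroup's 2x2 table is tested
  in the tail of the observed imbalance (point mass included), matching
  a single reported p per lineage. For haplogroup-by-STS deletion
  enrichment the test is a two-sided exact binomial against the
  proportional expectation: expected counts are small, and the source
  names no test — this is a documented choice, not an inference.
* **Reported means** round half-up to one decimal, and a "fold increase"
  is the ratio of the two rounded means, rounded again (this convention
  reproduces the published 3.2-fold from 11.7 vs 3.7). Note that
  one-decimal rounding of the qualified-STS retention (1787/2260 =
  79.07%) gives 79.1 where the source prints a truncated 79.0.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates a full synthetic cohort: catalog, raw depth
matrix, haplogroup marker genotypes, metadata and per-pair truth. Depth
is negative-binomial noise around
`base_depth x scale_i x efficiency_j x copy_factor x residual`, with

* log-normal per-STS capture efficiency (`sdlog` 0.25) and per-sample
  scale (`sdlog` 0.15), means 1;
* multi-copy STSs at 2x relative efficiency (total efficiency
  renormalized so `base_depth = 38.25` stays the cohort mean), with
  silent single-copy loss (depth halves, no deletion) exercising the
  merge skip rule;
* residual depth fraction 0.05 at truly deleted STSs;
* NB size 50, i.e. ~21% depth CV at nominal depth. An early development
  default of size 10 (~33% CV) produced a world whose classes overlap in
  all three predictors — incompatible with the reported behaviour of the
  real assay (a 97.8% PCR validation rate, no false calls at the control
  STSs sY84/sY86 across 1449 samples, perfect training resubstitution).
  The default was revised once to match that stated world and is frozen;
  the dispersion remains a documented free parameter.
* deletion architecture: a founder three-STS b2/b3-like deletion carried
  by every haplogroup-N sample, rare long contiguous deletions in cases
  (probability 0.5, mean 30 STSs), scattered singletons everywhere, and
  a short recurrent two-STS deletion in controls — approximately 5% of
  pairs deleted under the defaults.

The simulator does **not** emulate GC-dependent capture bias along the
genome, mappability structure, the real amplicon sequence of the MSY,
read-level artifacts, or linkage between haplogroups and anything beyond
the planted founder deletion. A green pipeline test therefore
establishes that the *algorithmic chain* recovers planted signal under
realistic noise — not that the method's published error rates transfer
to any particular real cohort. In particular, exact zero false calls at
the control STSs is a property of the real data's very low per-pair FP
rate; at the simulator's 21% depth CV the expected FP count over ~400
control-STS pairs is of order one, and the test suite checks consistency
with the global FP rate rather than literal zero.

The 134-event training draw (`make_training_subset()`) emulates a
PCR-validated training set from at most 26 samples "covering different"
predictor values: quotas over depth/RMD deciles spread across
log-probability terciles. A prevalence-mix draw
(`mix = "prevalence"`) is available; the stratified draw is the default
because an unstratified 5%-prevalence draw leaves the deleted regime of
the predictor space nearly unrepresented at n = 134.

## Known limitations

* Copy-number loss at multi-copy STSs is out of scope by design (the
  skip rule exists precisely because such losses do not produce a depth
  dropout the classifier is trained to see).
* The shipped haplogroup tree carries placeholder marker ids (synthetic);
  real marker curation (ISOGG-style) is the user's responsibility, and
  the tree file format is deliberately editable JSON.
* Recurrent merged deletions are keyed by exact member-STS set; partial
  overlaps between samples count as distinct deletions.
* Boundary estimates are bounded by probe geometry: `inner` coordinates
  are exact to the outermost deleted STSs, `outer` to the flanking
  non-deleted evidence, and nothing finer is claimed.

## A minimal run

```{r pipeline, eval = FALSE}
sim <- simulate_cohort(sim_scenario(seed = 1))
qcres <- run_qc(sim$depth)
feats <- compute_features(qcres$matrix)
set.seed(1001)
training <- make_training_subset(sim, feats)
model <- train_classifier(training)          # shipped C = 2^9, sigma = 2^3
calls <- classify(model, feats, dm = qcres$matrix)
intervals <- merge_calls(calls, sim$catalog)
call_accuracy(calls, sim$truth)
```

Every number the package reports is recomputed at run time by the test
suite (`tests/testthat/`) and the acceptance script
(`scripts/acceptance.R`); this vignette states no empirical result that
those do not themselves compute.
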