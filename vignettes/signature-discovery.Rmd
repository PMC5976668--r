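---
title: "Minimum-size gene signatures: model, choices, and limitations"
author: "frsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-size gene signatures: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frsig)
```

## The problem and the model

Given a log2 expression matrix (genes × samples) and a binary phenotype,
the goal is the *smallest* gene subset whose leave-one-out
cross-validated (LOOCV) accuracy with a nearest-neighbor classifier is
maximal. The pipeline has four stages.

**1. Per-gene scoring.** Fisher's ratio
$FR_j = (\mu_{j1}-\mu_{j2})^2/(\sigma_{j1}^2+\sigma_{j2}^2)$ scores each
gene's class separability; the log2 fold change
$FC_j = \mu_{j1}-\mu_{j2}$ gives direction and magnitude. $FR_j$ is
location- and scale-invariant and symmetric in the classes; it is zero
iff the class means coincide, and defined as `Inf` ("infinite
separability") in the degenerate case of zero total variance with
distinct means so such genes sort above all finite ratios.

**2. Band selection.** An optional filter keeps genes with
$FR \in [fr_{min}, fr_{max}]$ and $FC$ inside at least one of a list of
closed intervals. Both bounds of every interval are inclusive — bracket
notation is read as closed intervals. The window is always a user input:
there is no principled way to infer it from the data, and the upper FR
bound of a published window may simply be the observed maximum.

**3. Minimum-size signature.** Candidates are ranked by descending $FR$
(ties broken lexicographically by gene identifier, so ranking is a
deterministic permutation). "Recursive elimination of lower
discriminatory genes" is implemented as a prefix search: the LOOCV
accuracy of the top-$k$ prefix is evaluated for $k = n, n-1, \dots, 1$,
and the smallest $k$ attaining the maximum observed accuracy is
returned, together with the full accuracy curve. The classifier is
1-nearest-neighbor with Euclidean distance on the selected genes' log2
values ("the reduced base"); $k$ (odd) and a correlation metric are
exposed as options, and an optional z-scoring mode standardizes genes
using training-fold statistics only. No rescaling is applied by default
because all features are log2 intensities on a common scale.

**4. Network sampler.** Random gene subsets (size uniform on a range,
genes uniform without replacement) are drawn from the candidate pool and
scored by LOOCV; subsets at or above a retention accuracy are kept, and
each gene's posterior sampling frequency (fraction of retained subsets
containing it) measures how consistently it participates in accurate
predictors. All draws come from one seeded RNG stream *before* any
scoring, so results are reproducible regardless of how scoring is
executed or parallelized.

## Tunable parameters

| parameter | default | units / rationale |
|---|---|---|
| `var_type` | `"unbiased"` | within-class variance with $n-1$ denominator; the maximum-likelihood ($n$) form is a toggle and only rescales ratios by a common factor when class sizes are equal |
| `k` | 1 | neighbors; odd so a two-class vote cannot tie |
| `metric` | `"euclidean"` | squared distances on log2 values; `"correlation"` (1 − Pearson over the gene profile) needs ≥ 2 genes |
| `scale` | `FALSE` | optional per-gene z-scoring computed on training folds only, so no information leaks from the held-out sample |
| sampler `size_min:size_max` | 2–20 | small "networks", the regime where posterior frequencies are informative |
| sampler `n_draws` | 10 000 | Monte-Carlo resolution of the frequencies |
| sampler `retention_accuracy` | — | a natural pipeline default is the minimal signature's accuracy minus $1/n$ |

## Numerical and tie-breaking choices

* Distance ties in the nearest-neighbor search go to the
  lower-indexed training sample (`order()` is stable), making every
  accuracy an exact multiple of $1/n$ and every run deterministic.
* Equal-accuracy subset sizes: the smallest wins ("minimum-size").
* Differential expression is the per-gene equal-variance two-group
  ANOVA $F$-test with 1 and $n-2$ degrees of freedom ($F = t^2$),
  followed by Benjamini–Hochberg adjustment; the equal-variance form is
  used because the method is an ANOVA, not a Welch test. Degenerate
  genes: zero within-group variance with equal means gives $p = 1$ (no
  evidence); with unequal means, $p$ is set to the smallest positive
  double and a warning is raised rather than reporting an exact zero.
* Quantile normalization (the matrix-level stand-in for the quantile
  step of RMA) maps every column onto the row-wise mean of the sorted
  columns with average-rank tie handling, via
  `limma::normalizeQuantiles(ties = TRUE)`; it is idempotent up to
  floating tolerance.
* Batch correction is per-gene batch-mean centering with the grand mean
  added back — the exact least-squares solution of a one-factor batch
  model with no covariates. It preserves each gene's grand mean exactly
  and equalizes per-gene batch means exactly.
* Scoring and selection run *after* batch correction by default; the
  stage order is configurable in `pipeline_config()` since the original
  ordering of these operations is not fully determined.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` emulates a two-class microarray study:
Gaussian log2 intensities (the standard idealization of RMA-normalized
data) with grand mean 7 and within-class standard deviation 0.45;
unequal class sizes 12 vs 24 (the fatigued / non-fatigued design the
package is modeled on); 54,675 probe sets (HG U133 Plus 2.0 scale); a
configurable number of planted genes whose class-1 mean is shifted by
`effect_size` log2 units; additive per-batch sample offsets shared
across genes (the simplest structure that batch-mean centering provably
removes); and FACT-F baseline/1-year pairs drawn so that the ≥3-point
rule reproduces the class labels exactly (baseline uniform on the
integers 30–50; decrease uniform on 3–8 for fatigued, −3–2 for
non-fatigued — supports chosen so the instrument's 16–53 range is never
violated and any distribution satisfying the rule suffices).

The defaults `effect_size = 0.6` and `sigma_within = 0.45` place planted
genes at a population Fisher's ratio of $0.6^2/(2\cdot0.45^2)\approx0.89$
and fold change 0.6, i.e. inside the selection windows FR [0.70, 1.72]
and FC [0.09, 1.13] used in the reference analysis; 420 planted genes
mirror the size of that analysis's selected pool.

Not emulated: probe-level (CEL) structure and background; heavy-tailed
or gene-correlated noise; gene–gene covariance; batch effects that
interact with genes; covariates such as CRP or PSA; longitudinal
trajectories. Passing tests on this generator therefore demonstrate the
*algorithmic* correctness and calibration of the stages, not robustness
to the full messiness of real microarray data.

## Design choices that were genuinely open

* *Nearest neighbor, not an LDA projection.* The methodology is
  operationally defined by Fisher's-ratio ranking plus a
  nearest-neighbor class assignment in the reduced base; a Fisher LDA
  projection step before neighbor assignment is a plausible alternative
  reading, left as an extension point rather than a default.
* *Fold change as a log2 mean difference,* not a linear ratio: published
  selection windows of magnitude < 2 straddling zero are consistent
  with log2 differences.
* *Prefix elimination.* "Recursive elimination of lower discriminatory
  genes" is read as peeling single genes from the bottom of the ranked
  list, so every candidate signature is a top-$k$ prefix and the search
  is exhaustive over prefixes.
* *Sampler defaults.* Subset-size law, draw count and retention rule are
  not prescribed by the method's description; uniform sizes, uniform
  draws and an accuracy threshold are the minimal faithful reading of
  "networks of highly discriminatory genes", and all are configurable.

## Problem sizes used in the test suite

The suite exercises: oracle equivalence of Fisher's ratio on 1000 random
instances (tolerance $10^{-12}$); LOOCV against exhaustive hold-one-out
enumeration on all two-class labelings (≥ 2 per class) of 6-sample,
3-gene matrices; prefix-search optimality against brute-force
enumeration for ranked lists of ≤ 10 genes; parameter recovery on
2000-gene, 10-planted simulations over 25 seeds; sampler enrichment with
500–2000 draws; and null calibration at 5000–10,000 genes with 200 label
permutations (expected permuted-label 1-NN accuracy
$(n_1(n_1-1)+n_2(n_2-1))/(n(n-1))$, tested within three standard
errors). These sizes were chosen as the smallest at which the
statistical properties under test are stable.

## Known limitations

* In strong-signal regimes the minimum-size tie-break returns *very*
  small signatures (often 1–5 genes): once a few top genes reach the
  maximum LOOCV accuracy, no larger prefix can be chosen. That is the
  intended semantics, but it means the signature's *size* is not a
  robust measure of how many informative genes exist — the sampler's
  posterior frequencies are the better instrument for that question.
* LOOCV accuracy of a signature selected by optimizing LOOCV accuracy
  is an optimistically biased estimate of generalization; an outer
  validation loop is out of scope here.
* Accuracies are multiples of $1/n$; with 36 samples the resolution is
  2.8 percentage points, so nearby subset sizes frequently tie.
* The preprocessing stages are matrix-level stand-ins: full RMA
  (background correction, probe-level median polish) requires probe
  data and is out of scope.
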