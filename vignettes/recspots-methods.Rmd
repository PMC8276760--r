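---
title: "Methods: hot/cold spot classification in recspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hot/cold spot classification in recspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`recspots` classifies fixed-width genomic windows as meiotic
recombination hotspots or coldspots. The model is a standard binary
supervised-learning pipeline; the scientific content lies in how the
benchmark is defined and how windows are turned into features.

## Benchmark definition

Hotspots are taken as given intervals (peak calling is out of scope —
published hotspot sets are the intended input). Coldspots are defined
*operationally* from a per-base Spo11-oligo signal: every maximal run
of consecutive positions with value exactly zero and length ≥ 500 bp.
The strictness of "exactly zero" is deliberate: uncovered positions in
a bedGraph are materialized as zeros on reading, so "no signal" and
"zero signal" coincide, and regions with any detectable Spo11 activity
never enter the negative set. Runs are maximal, never tiled: a 1200-bp
zero run is one coldspot.

Each spot is recentered into a window of exactly `width` bp (default
1000) around the floor midpoint `c = ⌊(start + end)/2⌋` (0-based
half-open arithmetic; internally the package stores 1-based closed
`GRanges`, converting BED at the boundary). Windows that would cross a
chromosome end are dropped, not clipped, so every sample has identical
geometry — the fixed-span feature summaries below assume it.
Overlapping hot and cold windows are both kept; no deduplication is
attempted.

## Feature extraction

All sequence features are computed on the forward reference strand.
Strand orientation of asymmetric statistics (GC skew) is therefore a
declared convention, not a biological claim.

**Compositional profiles.** GC content, GC skew and dinucleotide
mutual information are computed in sliding windows of 100, 100 and
200 bp respectively, step 1 bp, each value assigned to the window
center. Only fully contained windows are evaluated (no edge padding).
Each profile is summarized over the central 300 bp as mean and sample
variance (n − 1): the variance is the package's measure of how much a
statistic *varies* across the spot, which for anti-symmetric patterns
(skew flipping sign at the center) carries the signal that the mean
cancels away.

Degenerate windows are handled explicitly: a window with no G or C
emits skew 0 with a warning (keeping profile length deterministic);
all-N windows emit `NA` and are excluded from summaries.

**k-mer composition** is computed on the central 300 bp (150/500 bp
supported), counting at step 1 and skipping N-containing words. For
k ≤ 2 raw frequencies are used; for k ≥ 3 add-one (Laplace) smoothing
`p_t = (N_t + 1)/(ΣN + 4^k)` avoids zero probabilities in short
sequences. k = 4 is the default k (the best-performing size), giving
the 96 + 256 feature layout checked by the test suite.

**Structural profiles.** Every structural property is a k-mer → value
lookup (k = 2 dinucleotide properties, k = 5 pentamer shape), mapped
along the sequence, smoothed with a 10-bp valid-mode moving average,
and summarized as central-span mean and variance. Whether a property
is per-base-pair or per-step is metadata; it does not change the
arithmetic. N-containing steps become missing values that propagate
through smoothing and are excluded pairwise from summaries — the
package never fabricates a parameter value.

The bundled nearest-neighbor thermodynamic table (ΔG°37/ΔH°/ΔS°,
kcal/mol and cal/(mol·K)) uses the published unified parameter set
expanded by reverse-complement symmetry. The pentamer shape,
electrostatic-potential, rigidity and the two 12-property
base-pair-step tables are *synthetic stand-ins*: deterministic draws
with realistic means and spreads, clearly labelled as such. The
package's claim is about the lookup–smooth–summarize chain and the
feature bookkeeping, not about specific published parameter values;
measured tables drop in via `loadParameterTable()`.

**Chromatin signals** contribute one feature per track: the plain mean
over the central 300 bp. No variance (profile variance of sequencing
coverage mostly reflects depth), no normalization or log transform —
tracks are taken as processed, and the choice of input normalization
is the user's.

## Classifiers and evaluation

Five classifiers run behind one interface, with decision values
defined per algorithm: positive-class probability (RF, LR, NB, CART)
or signed margin oriented toward the hot class (SVM).

* Random forest: 130 trees, `⌊log2 m⌋` candidate features per split.
* SVM: linear kernel, cost 1, feature scaling on (the library
  defaults of e1071 are the documented defaults here).
* Logistic regression: plain unregularized logit; perfect separation
  is caught by an iteration cap with a warning.
* Gaussian naive Bayes: implemented in-package because the pipeline
  needs a variance floor — constant features (common among rare
  k-mers) would otherwise make the Gaussian density degenerate. The
  floor (1e-9) is applied per class-feature pair with a warning, so
  the degeneracy is logged, never silent.
* CART: Gini splits, cp = 1e-6.

Cross-validation is stratified (the 3600/2538 class imbalance of real
benchmarks makes unstratified folds noisy) with folds dealt
round-robin after a seeded shuffle, so fold sizes differ by at most
one per class. Out-of-fold decision values are pooled into a single
ROC; AUC is the rank-based Mann–Whitney statistic with half-credit
ties. The hold-out split (default 70/30) is stratified with per-class
rounding. All randomness flows from explicit seed arguments; there is
no hidden global RNG state (the internal helper saves and restores
`.Random.seed`).

## Feature selection

Two procedures operate on a ranking:

* **ANOVA F ranking** — between- over within-group variance, two
  groups. Constant features score 0 (no information, ranked last);
  zero within-group variance with real separation scores +Inf (ranked
  first, logged). Ties break by feature name.
* **Gini ranking** — mean Gini decrease from an RF (130 trees) on the
  full matrix.

**Incremental feature selection** walks the ranking, keeping a
feature only if pooled CV accuracy *strictly* increases — strict
rather than ≥ because the goal is the smallest set, and ties would
otherwise accumulate free riders. The fold assignment is frozen once
per run so every step sees identical folds (isolating the feature
effect from fold noise); the top-ranked feature always seeds the set.

**Correlation pruning** repeatedly removes, from the currently most
correlated pair (by |Pearson r| — strong anti-correlation is equally
redundant), the member with the lower univariate CV accuracy on the
same frozen folds, recording full-set accuracy after each removal
until one feature remains. Constant features have undefined
correlations and are treated as r = 0 (logged). The trace, not a
truncation rule, is the output: the expected signature on redundant
sets is that early removals barely move accuracy while late ones
degrade it.

# The synthetic benchmark

The generator emulates the *contrasts* the classifier is supposed to
exploit, at desk scale:

* anti-symmetric GC skew flipping sign at the hot-spot center
  (amplitude 0.3 by default, applied as a ±a multiplicative transfer
  between G and C probabilities with renormalization);
* central A/T excess (mixing weight 0.15 toward pure A/T over the
  central 100 bp);
* a central alternating-dinucleotide bias (0.2) that creates a
  mutual-information peak;
* per-mark fold-changes over hot windows (3 for H3K4me3, 2 for
  H3K56ac and Top2, 0.5 for MNase — a nucleosome-depletion dip) on
  Gaussian noise of SD 0.2 around baseline 1, negative draws clipped
  at 0;
* a Spo11-like track: strictly positive background noise, elevated
  over hot windows, exactly zero across cold windows.

Cold windows are pure background rather than an anti-signature,
matching the view of coldspots as featureless. Default geometry is
4 × 400 kb with 300 + 300 windows — the package's standard study
conditions; tests use smaller geometries where the property under
test allows it (the calibration/recovery checks use the full 600
spots; selection-procedure checks use 120-sample, 23-feature
matrices over 10 seeds).

What the generator does **not** emulate: realistic yeast base
composition and chromosome structure (promoters, replication origins,
rDNA), spot-length variation, read-level noise, correlated marks, or
mapping artifacts. Passing tests therefore demonstrate that the
machinery is correct and calibrated (null inputs give chance-level
AUC; planted effects are recovered), not that any particular accuracy
will transfer to real data.

All generator randomness derives from one root seed via fixed
per-component substreams, so genome, tracks and placements are
individually reproducible.

# Numerical choices

* Coordinates: 1-based closed `GRanges` internally; BED and bedGraph
  converted on read/write. Centering arithmetic is defined (and
  tested) in 0-based half-open terms.
* Variance is always the n − 1 sample variance.
* Central-span membership uses |offset| ≤ span/2 with a 1e-9 slack to
  absorb float drift in position bookkeeping.
* Moving averages run in valid mode via cumulative sums; constant
  inputs can acquire ~1e-16 rounding noise, which matters only when
  asserting exact zeros.
* Overlapping bedGraph intervals are rejected rather than summed —
  an overlap almost always signals a malformed file, and silently
  summing would corrupt the zero-run coldspot rule.
* Seeds are kept below 2^31; derived substream seeds use a fixed
  affine map modulo a large prime.

# Known limitations

* Hotspot peak calling is not implemented; hotspots must be supplied.
* The published coldspot count for the real benchmark cannot be
  reproduced here because it depends on the external Spo11-oligo map;
  only the rule is implemented.
* Structural features depend on the parameter tables supplied; the
  bundled synthetic tables support testing, not biological
  interpretation.
* The logistic model is fit by unpenalized IWLS and relies on rank
  handling plus an iteration cap under separation or severe
  collinearity; for p approaching n a penalized fit would be more
  stable but would change the model.
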