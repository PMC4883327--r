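---
title: "Methods: e-nose quality classification of rose essential oils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: e-nose quality classification of rose essential oils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosenose)
```

# The problem

Grading *Rosa damascena* essential oil is conventionally a GC-MS exercise:
the percent of six key volatiles — phenyl ethyl alcohol, trans rose oxide,
citronellol, nerol, geraniol, geranial — is summed, and the oil is called
low quality below 10%, middle between 10% and 50%, and high at 50% or
above. An electronic nose replaces the chromatograph with seven partially
selective MOS gas sensors whose resistance transients, taken together,
fingerprint the headspace. The statistical task is then a three-class
classification of 49-dimensional feature vectors, with GC-MS supplying the
reference labels. This vignette documents the models, the tunable
parameters, the numerical conventions, and the design decisions behind
each stage of the package.

# Reference labels from GC-MS

`label_dataset()` applies the threshold rule to a constituent table.
Two conventions worth noting:

* **Boundaries are half-open**: `[0,10) -> C1`, `[10,50) -> C2`,
  `[50,Inf) -> C3`, so a total of exactly 10 is middle and exactly 50 is
  high quality. No genotype in the packaged reference panel sits on a
  boundary, so the choice is inconsequential there; it is fixed so the
  three intervals partition `[0, Inf)` exactly.
* **Name matching** is case-insensitive and whitespace-normalized, because
  published composition tables mix capitalizations; absent constituents
  (often printed as `-`) count as zero.

The packaged panel (`rose_constituent_table()`) lists 56 volatiles for ten
genotypes. Summing the six key rows labels g1–g4 low, g5–g7 middle and
g8–g10 high quality. One quirk: the g7 column sums to 37.38 while the
panel's printed total row shows the one-decimal rounding 37.4; the package
always recomputes totals from the per-constituent rows.

# Transient features

One measurement cycle is 760 s: 60 s clean-air baseline, 200 s sample
injection, 500 s purge recovery (`phase_schedule()`, boundaries half-open
on the right). From each sensor's resistance trace `extract_features()`
computes the seven canonical MOS descriptors built on the baseline
resistance `Ri`, the injection plateau `Rf`, and the conductances
`Gi = 1/Ri`, `Gf = 1/Rf`:
`f1 = Ri/Rf`, `f2 = Ri − Rf` (Ω), `f3 = (Ri − Rf)/Ri`, `f4 = Gf − Gi` (S),
`f5 = (Gf − Gi)/Gi`, plus the response time `f6` and recovery time `f7`.

Estimator choices, all config-exposed:

* `Ri` is the mean over the **last 30 s of baseline** (robust to initial
  settling); `Rf` the mean over the **last 20 s of injection** (the
  plateau rather than the within-phase extremum — with first-order
  kinetics and the default time constants the two coincide to ~1e-4
  relative).
* `f6` is measured from injection start (60 s) to the first crossing of
  90% of `ΔR = Ri − Rf`; `f7` from purge start (260 s) to the first
  return within 10% of `ΔR` of baseline. Crossings are located by linear
  interpolation between samples, giving deterministic sub-sample
  resolution. A never-crossed threshold yields the full phase duration
  with a warning rather than an error, so a sluggish sensor degrades
  gracefully.
* Algebraic identities tie the set together (`f5 = f1 − 1`,
  `f3 = 1 − 1/f1`, `f4 = f2/(Ri·Rf)`); the test suite checks them to
  1e-9 relative tolerance on randomly generated transients.

`normalize_columns()` divides each feature column by its maximum — the
convention that keeps zero at zero and suits nonnegative,
resistance-decreasing MOS responses, and that delivers the [0, 1] inputs
Fuzzy ARTMAP requires. An all-zero column stays zero. Should a column
contain negative values (an oxidizing response), divide-by-max cannot
bound it, so that column falls back to min-max scaling with a warning.
The per-column statistics are stored so the identical transform can be
replayed on held-out rows, which are then clipped to [0, 1].

# Fisher-ratio ranking

`fisher_ratio()` scores one feature as external over internal variance:
the variance of the class centroids divided by the average within-class
variance. The definition names the quantities but not the divisors; the
defaults use the population variance (divide by the number of classes,
and by the class size within classes) and the **unweighted** mean across
classes, matching the "average variance inside each category" reading.
Sample-variance conventions are available; with equal class sizes the
induced ordering is identical, and the suite asserts this.

Degenerate columns are flagged rather than silently dropped: zero
internal variance with separated centroids scores `Inf` (sorted first),
a constant feature scores `NaN` (sorted last); ties keep ascending column
order, so rankings are fully deterministic. The ratio is scale- and
shift-invariant, which also settles an otherwise open question — ranking
before or after normalization gives the same order, so the package ranks
the normalized matrix.

# Fuzzy ARTMAP

The classifier is the category-prediction (simplified) form of Fuzzy
ARTMAP: a fuzzy ART category module whose committed categories map
directly to class labels through the map field. The full second ART
module is unnecessary when targets are discrete labels — with one-hot
class patterns, any map-field vigilance above 0.5 reduces the map-field
test to exact class agreement, which is how `rho_ab = 0.99` ("nearly 1")
is implemented.

Hyperparameters (`artmap_hyperparams()`), with the study settings as
defaults:

| parameter | default | role |
|---|---|---|
| `rho_a_baseline` | 0 | baseline vigilance; 0 permits the coarsest categories, refined only on predictive error |
| `rho_ab` | 0.99 | map-field vigilance; behaves as exact class agreement |
| `alpha` | 0.001 | choice parameter; well below 1 to avoid competition ties |
| `beta` | 1 | fast learning: one presentation fully commits a category |
| `epsilon` | 0.001 | MT+ match-tracking increment (the increment size is a free choice; any small positive value behaves identically on continuous data) |
| `max_epochs` | 10 | upper bound; training stops when a full pass changes nothing (fast learning typically stabilizes in 1–3 passes) |

Deterministic conventions: category competition breaks ties to the lowest
index; the uncommitted node competes alongside committed categories and
loses exact ties to them; patterns are presented in dataset order by
default, with an optional seeded shuffle since ARTMAP is order-sensitive.
Training is entirely deterministic — identical data and order give
identical models. Weights can only shrink (`w <- I ∧ w` under fast
learning), which yields the stability property the suite asserts:
re-presenting a stabilized training set changes nothing, and recall on a
consistent training set is 100%.

# Multiclass LDA

`fit_lda()` builds the pooled within-class scatter `Sw` and the
size-weighted between-class scatter `Sb` and takes the leading
eigenvectors of `Sw^{-1} Sb`, computed through the symmetric whitening
`Sw^{-1/2} Sb Sw^{-1/2}` for numerical stability. With three classes at
most two discriminant directions exist; their `explained_ratio` is
non-increasing. Numerical choices:

* `Sw` can be singular at p = 49 features on 149 training rows, so a
  small ridge `lambda = 1e-8 · trace(Sw)/p` is added and the inverse
  square root truncates eigenvalues below `1e-12` of the largest
  (a pseudo-inverse). `lambda` is configurable, including 0.
* Eigenvector sign is fixed (largest-magnitude loading positive) so
  LD1/LD2 score plots are reproducible run to run.
* Classification uses the equal-covariance Gaussian rule — prior-adjusted
  Mahalanobis-nearest centroid in the full discriminant space, not
  per-LD thresholds, since neither LD separates all three classes alone.
  Priors default to the empirical frequencies (60/45/45 is unbalanced);
  exact score ties go to the larger prior, then the lower class index.

An independent reference implementation (`MASS::lda`) serves as a
cross-check oracle in the test suite, never as the implementation.

# Leave-one-out evaluation

`loocv()` runs one fold per measurement in row order: train on n − 1,
predict the held-out row, accumulate a confusion matrix with rows = real
and columns = predicted class. `run_experiment()` crosses both
classifiers with subset sizes k ∈ {10, 20, 30, 49}.

Two protocol modes:

* **Study-faithful (default)**: the column normalization and the Fisher
  ranking are computed once on the full 150-row matrix, before any fold
  is held out. This leaks the held-out row's contribution to the column
  maxima and the ranking into its own fold — it is how the original
  protocol reads, and the package reproduces it deliberately.
* **Fold-safe** (`fold_safe = TRUE`): each fold recomputes normalization
  statistics and the top-k ranking from its 149 training rows only and
  replays them onto the held-out row. The leakage choice is thus exposed,
  not hidden.

Success rates are stored at full precision and printed rounded to whole
percents (half-up, via R's `round`); a rate of 81.33% therefore prints as
81%, and the JSON report always carries the exact value. Reports omit
timestamps from their JSON serialization so identical configurations
produce byte-identical files.

# What the synthetic generator emulates

No raw sensor recordings from the original campaign are publicly
deposited, so the package generates them. The generator is first-class,
tested code, and its defaults are the study conditions: 10 genotypes × 15
replicates = 150 measurements on 7 sensors over the 760-s cycle, sampled
at 1 Hz (the acquisition rate is not documented; 1 s is exposed as
`sample_period_s`).

The response model, per sensor and measurement:

* **Kinetics**: piecewise first-order exponentials — baseline at `Ri`,
  injection relaxing toward `Rf = Ri(1 − d)` with time constant
  `tau_rise` (default 20 s), recovery relaxing back with `tau_recovery`
  (default 80 s). This is the simplest standard MOS approximation that
  exposes all seven features; real transients are only qualitatively
  documented. Time constants scale mildly with depth
  (`tau · (1 + 0.5(d − 0.5))`): deeper responses mean more adsorbed
  analyte and slower kinetics, which gives the time features genuine,
  class-correlated information.
* **Response depth** `d` combines four factors: the sensor's class-mean
  depth from a 7 × 3 sensitivity matrix; a power-law concentration factor
  `(total/class-mid)^0.5` tying the response to the genotype's actual
  key-constituent total; a fixed per-genotype multiplicative scatter
  (`genotype_cv = 0.08`) giving each genotype its own fingerprint; and
  per-measurement jitter (`depth_jitter_cv = 0.015`). Depths clamp to
  (0.02, 0.95).
* **Noise** is multiplicative log-normal on every sample
  (`noise_cv = 0.01`), mean-one so that `noise_cv = 0` reproduces the
  closed form exactly — a property the tests assert sample by sample.
* **Reproducibility**: a single root seed drives everything; each
  genotype and each measurement draws from its own counter-derived
  substream, so any subset of the campaign regenerates identically.

The default sensitivity matrix encodes partially selective, overlapping
sensors: three respond monotonically with the key-constituent total
(S1, S4, S6 — solvent/alcohol-type sensors), two carry a middle-quality
signature (S3, S7), two are nearly class-blind (S2, S5). Combined with
the concentration coupling this produces the regime the comparison is
about: classes form tight replicate clusters per genotype (good for an
adaptive-resonance memory), but class means fall along a low-dimensional,
roughly ordered continuum whose boundaries blur where a genotype's total
approaches a threshold — exactly where a pooled-covariance linear method
loses accuracy. The separability defaults were calibrated across several
seeds so that this qualitative ordering (ARTMAP at least matching LDA in
every cell, and staying above 95% at k = 10) is a robust property of the
conditions rather than an artifact of one random draw.

What the generator does **not** emulate: multi-day sensor drift and the
daily ethanol recalibration, humidity/temperature covariates, oxidizing
(resistance-increasing) responses, and non-first-order kinetics. Passing
tests on synthetic data therefore demonstrate correctness of the
pipeline's statistics and algorithms under controlled conditions — not
that any particular accuracy level transfers to a physical instrument.

# Problem sizes and runtime

The shipped tests and the acceptance script run the full 150-measurement
campaign: 150-fold LOOCV across the 2 × 4 classifier/subset grid
(1,200 classifier fits) completes in well under a minute on one CPU; the
byte-reproducibility check uses a reduced 50-measurement campaign with
two subset sizes. These sizes were chosen to exercise every code path at
the study's own scale.

# Known limitations

* The published headline accuracies depend on the original, undeposited
  recordings; the package reproduces the study's *procedures* and its
  in-table arithmetic exactly, and its qualitative findings on synthetic
  data, but cannot reproduce the original accuracy figures themselves.
* Fuzzy ARTMAP is order-sensitive; only dataset order and a seeded
  shuffle are provided, not order optimization.
* The LDA ridge default is adequate for 49 features but is not a tuned
  shrinkage estimator; heavy regularization regimes (p ≫ n) are out of
  scope.
* `beta < 1` (slow recoding) is supported but untuned; distributed and
  ART-b-clustering ARTMAP variants are out of scope.
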