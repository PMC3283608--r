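---
title: "PhysChemAAC: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PhysChemAAC: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: the encoding, the
two-level classifier, the evaluation protocols, the synthetic-data
generator, and every place where the design was genuinely open and a choice
had to be made. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## 1. The physicochemical encoding

### 1.1 Property scales and standardization

Ten amino-acid scales are embedded as constants (`referencePropertyTable()`,
version `reference-1.0`): hydrophobicity, hydrophilicity, side-chain mass,
pK1 (α-COOH), pK2 (NH3), isoelectric point at 25 °C, average buried volume,
molecular weight, side-chain volume, and mean polarity. Before use, every
scale is standardized over the 20 native amino acids:

$$z_r = \frac{x_r - \bar{x}}{\sigma(x)},$$

with the **population** standard deviation (divisor 20, not 19). The
20-residue alphabet is the complete population of the scale, not a sample
from it, so the population form is the statistically coherent choice; the
conversion is idempotent under either convention, but the numeric values
differ, and the tests pin the population form. Residue order is fixed
alphabetical by one-letter code (A, C, D, …, Y) in every table and
serialization.

Custom user tables go through the same constructor (`propertyTable()`) and
standardization; a scale whose 20 values are all equal has no defined
z-score and is rejected (`ZeroVarianceScale`). One embedded value worth
flagging: the isoelectric-point entry for asparagine (N) in the reference
table is 10.76, identical to arginine's, which is far from the textbook
value (≈ 5.4). The reference table reproduces its source data verbatim
rather than silently "correcting" it; users who prefer a corrected scale
can supply one through `propertyTable()`.

### 1.2 The ACC transform

A sequence of length $L$ becomes a $10 \times L$ matrix of standardized
property values, from which auto- and cross-covariance components are taken
at lags $g = 1..LG$:

$$\mathrm{AC}(i,g) = \frac{1}{L-g}\sum_{j=1}^{L-g}(z_{i,j}-\mu_i)(z_{i,j+g}-\mu_i),
\qquad
\mathrm{CC}(i_1,i_2,g) = \frac{1}{L-g}\sum_{j=1}^{L-g}(z_{i_1,j}-\mu_{i_1})(z_{i_2,j+g}-\mu_{i_2}),$$

with $\mu_i$ the full-sequence mean of row $i$. Design choices here:

* **Normalization $1/(L-g)$ and centering by the full-sequence row mean.**
  This is the standard ACC form used throughout the protein-descriptor
  literature; it makes the homopolymer encode to the exact zero vector and
  keeps each component an average over its $L-g$ product terms. The
  brute-force oracle tests pin this form to $10^{-12}$.
* **Maximum lag $LG = 10$.** With 10 properties the dimension is
  $10\,LG + 90\,LG = 100\,LG$; $LG = 10$ gives the 1000-dimensional
  descriptor space the classifier operates in. `EncoderConfig` exposes
  $LG$; the dimension law $P^2 LG$ holds for any property count $P$
  (a 9-property table gives 810 components).
* **All 90 ordered pairs.** Cross-covariance is direction-dependent
  (confirmed numerically in the tests), and both directions are kept —
  required to reach the 1000-component count.
* **Canonical component order.** AC block ordered by (property, lag), then
  the CC block by (property 1, property 2 skipping the diagonal, lag).
  The order is serialized in the feature-matrix header
  (`AC_PC1_lag1` … `CC_PC10_PC9_lag10`) so downstream consumers never guess.
* **Minimum length $L \ge LG + 1$.** Shorter sequences would leave some
  lags without a single product term; they are rejected
  (`SequenceTooShort`) rather than zero-padded, so every component is
  always well defined.
* **Non-canonical residues** (B, J, O, U, X, Z, `*`) are dropped with a
  counted warning. Imputing the standardized mean (0) would bias
  covariances toward zero over runs of unknowns. More than 10% ambiguous
  residues rejects the record; a strict mode turns any drop into an error.

## 2. The two-level classifier

Level 1 is a binary RBF-SVM (NR vs non-NR) trained on all samples; level 2
is a multi-class RBF-SVM trained on the NR samples only, combined by
one-vs-one voting (the convention of the underlying libsvm engine, reached
through `e1071`). A query predicted non-NR never reaches level 2.

* **Hyperparameters.** $(C, \gamma)$ per level come from a 2-D grid search
  maximizing stratified 5-fold cross-validation accuracy. Default grids are
  the usual coarse log2 grids, $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$.
  Ties prefer smaller $C$, then smaller $\gamma$ — the smoother model.
  Fold assignment is seeded and stratified, so the search is fully
  deterministic; classes smaller than the fold count reduce the fold count
  (with a warning) down to 2.
* **Feature scaling.** Per-feature z-scoring is fitted on the training
  slice (never on held-out data) and applied to queries. The RBF kernel is
  scale-sensitive and ACC components span orders of magnitude; without
  scaling a handful of high-variance components dominates the kernel.
  Toggleable (`featureScaling`), default on, pinned by the tests.
* **Class weighting** (inverse-frequency) exists as a flag but is off by
  default: the benchmark-shaped 159-vs-500 imbalance is handled adequately
  by the margin itself, and unweighted training keeps the decision
  comparable with the default libsvm behaviour.
* **Batch cap.** `predict()` accepts at most 500 sequences per call,
  mirroring the submission contract of the original web service; encoder
  failures are reported per record without aborting the batch.

## 3. Evaluation protocols

* **Jackknife of record.** Hyperparameters are fixed once by a grid search
  on the full dataset, then each sample is predicted by a model retrained
  on the remaining $n-1$. This mirrors the original protocol and makes the
  report unique — no randomness remains once $(C,\gamma)$ are fixed. The
  in-fold grid search is available (`strictSearch = TRUE`) for
  leakage-free estimates; the report's protocol string records it.
  A caveat worth knowing: with a *degenerate* classifier this protocol
  exhibits the classic leave-one-out artifact (the held-out sample's class
  is always the training minority, driving accuracy to 0 on balanced null
  data); the null calibration below therefore uses an imbalanced design.
* **Per-class metrics** in the multi-class task are one-vs-rest from the
  confusion matrix: ACC and the Matthews coefficient, with the convention
  MCC = 0 when any marginal factor vanishes. The overall MCC of a
  multi-class report is the standard multi-class generalization of the
  binary MCC (the $R_K$ statistic), which reduces to the binary MCC for
  two classes.
* **Impact ranking.** For each property, the data are re-encoded with the
  nine remaining scales ($81 \cdot LG = 810$ components), the grid search
  is refreshed, and the jackknife accuracy drop against the ten-property
  baseline is recorded; properties sort by drop, equal drops share a rank.
  At level 2 the ranking runs over NR samples only.

## 4. The synthetic-data generator

The generator exists so that training, evaluation and ranking are fully
testable without any download. It emulates the statistical premise of the
method — that related proteins share physicochemical structure — with two
separation-scaled mechanisms (weight $w = s/(1+s)$ for separation $s$):

1. **Composition tilt.** Class $c$ up-weights residues at one extreme of
   the mean standardized signal-property score, direction alternating by
   class (+, −, +, …) and magnitude growing every second class, mixed with
   the uniform background by weight $w$ (softmax sharpness β = 2).
2. **Two-phase Markov modulation.** Each residue is emitted from one of two
   phase profiles (score tilted up or down, sharpness α = 2 scaled by
   $w$), selected by a hidden two-state chain with class-specific switch
   probability $s_c \in \{0.05, 0.95, 0.35, 0.65, 0.20, 0.80, 0.50\}$.
   This imprints a geometric lag-covariance signature $\propto (1-2s_c)^g$
   — the quantity the ACC encoder actually measures — giving up to seven
   mutually distinguishable classes.

The second mechanism is there by necessity, not decoration: we first built
a pure i.i.d. composition-tilt generator and measured that the encoder
cannot separate such classes well, because centering by the sequence mean
cancels composition shifts exactly, leaving only variance-structure signal
attenuated by $1/L$ and confounded with sequence length (cross-validated
accuracy plateaued in the 0.65–0.85 range even at extreme tilt). Positional
covariance structure is what the ACC transform is built to detect, so the
generator provides it. At separation 0 both mechanisms vanish *exactly* —
every class draws uniform i.i.d. residues — which the null-calibration
tests rely on.

When `signalProperties` is a proper subset (e.g. only pK1), the phase score
is residualized against the other nine scales over the 20-residue space.
Property scales are mutually correlated across residues (hydrophobicity vs
polarity, mass vs volume), so without this projection a "single-property"
signal bleeds into every correlated scale and the leave-one-property-out
drop no longer isolates the intended property. With the projection, the
positional signature lives in the signal property's components only, which
is exactly what "only this property carries class signal" should mean.

Defaults mirror the benchmark shape: subfamily class sizes
(50, 36, 37, 7, 12, 5, 12) — so the small-class fold-reduction paths are
exercised (the NR6 analog has 5 members) — 159/500 for two-class sets, and
sequence lengths uniform on [50, 400].

What the generator does **not** emulate: real NR domain architecture (zinc
fingers, ligand-binding domains), homology structure between sequences,
length–class correlations, or realistic residue composition marginals.
Passing tests on synthetic data therefore demonstrate that the pipeline
recovers physicochemical class structure when it is present in the
covariance sense — not that any particular accuracy will be attained on
real proteomes.

## 5. Study conditions of the acceptance computations

`scripts/acceptance.R` (and the acceptance test file) run at fixed,
documented problem sizes chosen to exercise the full pipeline at desk
scale:

* **Strong-separation recovery.** Separation 4 ($w = 0.8$); level 1 on two
  classes of 100 sequences each, level 2 on three subfamilies of 100 each;
  lengths [50, 400]; grids $C \in 2^{-3..11}$, $\gamma \in 2^{-15..-3}$
  (log2 step 2). Thresholds: jackknife ACC ≥ 95% (level 1), ≥ 90%
  (level 2).
* **Null calibration.** Separation 0 with the benchmark-shaped imbalance
  scaled to 32 vs 100 and lengths [50, 150]; jackknife accuracy must fall
  inside the central 99% binomial band around the majority rate 100/132.
  The imbalanced design is deliberate (see the leave-one-out artifact
  above).
* **Impact ranking.** Two classes of 50, separation 1.5, lengths [80, 200],
  signal property pK1-only (`PC4`); the ranked drop of PC4 must be first.
  Separation 1.5 keeps the baseline below ceiling so the ablation is
  informative.
* **Oracle agreement.** 50 random sequences, lengths 11–60, every one of
  the 1000 components against an independent double-loop implementation at
  $10^{-12}$.

All dataset seeds derive from the script's `--seed`; the same seed
reproduces every number byte-for-byte.

## 6. Known limitations

* The original benchmark of 159 NRs + 500 non-NRs is no longer reliably
  downloadable, so the package's accuracy claims are property-based (on
  synthetic data) rather than benchmark reproductions; the headline rates
  published for the original predictor are not reproduced here.
* Encoding is composition-and-covariance only; no evolutionary information
  (profiles, PSSMs) or domain annotations are used.
* The jackknife protocol of record fixes hyperparameters on the full
  dataset first (as the original method did); this leaks a small amount of
  information relative to `strictSearch = TRUE`, which is slower by a
  factor of about the dataset size.
* Probability calibration, alternative kernels, and feature selection
  beyond the fixed encoder are out of scope.
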