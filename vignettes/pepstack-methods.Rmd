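---
title: "Composition-based peptide classification with a stacked ensemble"
author: "pepstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-based peptide classification with a stacked ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepstack)
```

## The problem

Interleukin-10 (IL-10) is an anti-inflammatory cytokine; some MHC class II
binding peptides induce its release and some do not, and identifying the
inducers experimentally is slow and expensive. The published benchmark for
this task is small and imbalanced — roughly 394 inducing against 848
non-inducing peptides of about 8–25 residues — which is exactly the regime
where sequence-composition features, oversampling and ensemble learning
earn their keep. `pepstack` implements that whole pipeline as reusable,
testable pieces: any binary peptide-classification problem with short
sequences and class imbalance fits the same mould.

## Feature encoders

All encoders are pure functions from a residue string to a fixed-length
named vector, with columns laid out in the alphabetical residue order
`A, C, D, ..., Y` (and its Cartesian powers). The registry
(`encoder_registry()`) exposes ten descriptors with these default lengths:

| encoder | length | what it measures |
|---|---|---|
| AAC | 20 | residue frequencies, count/L |
| DPC | 400 | adjacent ordered pair frequencies, count/(L−1) |
| TPC | 8000 | adjacent ordered triple frequencies, count/(L−2) |
| CKSAAP | 1600 | pair frequencies at gaps 0–3, per-gap blocks each summing to 1 |
| PAAC | 22 | composition + 2 sequence-order correlation terms |
| APAAC | 24 | composition + 2×2 amphiphilic correlation terms |
| CTDC | 39 | 3-group composition for 13 physicochemical properties |
| CTriad | 343 | conjoint-triad class 3-mer counts over 7 residue classes |
| Moran | 2 | hydrophobicity autocorrelation at lags 1–2 |
| RAACC | 4 | composition over a 4-cluster reduced alphabet |

Choices worth knowing about:

* **Pseudo compositions (PAAC/APAAC).** The sequence-order terms use the
  classic hydrophobicity, hydrophilicity and side-chain-mass tables bundled
  in `paac_properties()`, standardised to zero mean and unit population
  variance over the 20 residues. The defaults `lambda = 2`, `w = 0.05`
  reproduce the standard 22- and 24-component vectors. At `lambda = 0` both
  encoders reduce exactly to AAC, which the tests assert — a useful
  correctness anchor because the degenerate limit has a closed form.
* **CKSAAP.** The gap range 0–3 is fixed by the conventional 1600-length
  vector (4 blocks × 400 pairs); each block is normalised by its own count
  of eligible position pairs so each block sums to 1.
* **CTDC.** The 13 property partitions (seven hydrophobicity scales, van
  der Waals volume, polarity, polarizability, charge, secondary structure,
  solvent accessibility) are the descriptor-toolkit standards; a test
  verifies each is an exact partition of the alphabet.
* **CTriad.** Raw window counts are min-max scaled across the 343 bins,
  the descriptor's original normalisation; `normalize = "frequency"`
  divides by L−2 instead for users who want a proper composition.
* **Moran.** A length-2 descriptor needs one property and two lags; the
  bundled hydrophobicity scale is the documented default (configurable via
  `properties` and `nlag`). Zero-variance sequences (homopolymers) return 0
  rather than 0/0.
* **RAACC.** The default reduced alphabet is a fixed four-cluster
  partition — charged (DEHKR), polar (CNQST), large/aromatic hydrophobic
  (FILMVWY), small hydrophobic (AGP) — chosen as a conventional
  physicochemical reduction; alternative schemes can be added to
  `raac_scheme()`.

The modelling layer defaults to the combined `AAC + DPC` set (420
columns), the configuration that discriminates best in this family of
descriptors while staying small enough for the 1.2k-peptide scale.

## Class-imbalance correction

`adasyn_oversample()` and `smote_oversample()` both synthesise minority
points by interpolation, `s = x_i + λ(x_k − x_i)` with
`λ ~ Uniform(0, 1)` and `x_k` drawn from the k = 5 nearest *minority*
neighbours of `x_i`. They differ only in allocation: SMOTE spreads the
synthetic budget uniformly, while ADASYN weights each minority point by
the majority share of its k-neighbourhood in the full data, concentrating
synthesis near the class boundary. Largest-remainder rounding makes the
per-point allotments sum exactly to the budget
`G = ceil(N_maj · target_ratio) − N_min`.

Distances are Euclidean on the encoded features without rescaling:
composition features are already commensurate on [0, 1], so a scaler would
only reweight blocks arbitrarily. Every synthetic row's generating pair and
λ are logged in the returned `pairs` table, which is what lets the test
suite verify the segment contract directly rather than statistically.

**Where balancing happens matters.** The default protocol scope is
`fold-internal`: oversampling runs inside each training fold only, so no
synthetic point (whose parents may include test-fold information) can ever
reach a held-out set. A `global` scope — resample first, split second — is
available behind an explicit flag for comparison with workflows that
balance the whole dataset up front; expect it to flatter every metric.

## The stacking ensemble

Five base learners feed a logistic-regression meta-learner:

| kind | backend | non-default settings |
|---|---|---|
| random-forest | `ranger` | 300 trees, depth ≤ 30, min node size 5 |
| decision-tree | `rpart` | information-gain (entropy) splits, minsplit 5 |
| support-vector-machine | `e1071::svm` | RBF kernel, cross-validated probability calibration |
| k-nearest-neighbors | `class::knn` | k = 5, vote fractions as probabilities |
| gradient-boosting-machine | `xgboost` | 100 rounds, library defaults otherwise |

The gradient-boosting slot is backed by `xgboost`, the standard boosted-tree
implementation in R. `rpart` exposes no analogue of a randomised splitter,
so the decision tree is deterministic given the data; the entropy criterion
and minimum split size are honoured.

The meta-learner is trained on **out-of-fold** base predictions: the
training rows are split into 5 stratified internal folds, each base learner
is fitted 5 times on 4/5 of the data and predicts the held-out fifth, and
those cross-fitted probability columns (one per learner) form the
meta-feature matrix. Training the meta-learner on same-data base
predictions would let it exploit base-learner overfit — cross-fitting is
the standard reading of stacked generalisation and the package's default.
A `hard-label` meta-feature mode (thresholded at 0.5) exists for
comparison. After the meta-fit, each base learner is refitted on the full
training data for deployment.

All randomness flows from one master seed through a documented splitting
rule (`derive_seed()`), so refits are bit-reproducible; fitted models
persist to a single artifact file and reload with identical scores.

## Evaluation

Metrics are computed from the 2×2 confusion table at threshold 0.5:
sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy, and Matthews
correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

all reported as fractions in [0, 1] (MCC in [−1, 1]); a percent display is
a presentation choice left to the caller. Undefined sensitivity or
specificity (empty class in a fold) is reported as `NA`; an MCC with a zero
denominator is defined as 0. AUC uses the rank (Mann–Whitney) formulation
with ties counted half, so it is invariant under monotone score transforms.

Two protocols are built in: stratified 10-fold cross-validation and a
stratified 80/20 train/test split. Stratification deals each class
round-robin into folds, so per-fold class counts deviate from
proportionality by at most one instance. Cross-fold aggregation is the
unweighted mean of per-fold metrics (fold sizes are near-equal by
construction); pooled-confusion aggregates are also reported since the two
conventions differ slightly and readers of published tables rarely know
which they are looking at.

## The synthetic benchmark

Real IL-10 benchmark data is external to the package, so every stage is
exercised on synthetic peptides built to be *compositionally* separable —
the one kind of signal all bundled encoders can see. The generator tilts a
uniform residue baseline in opposite directions for the two classes on a
fixed ten-residue subset: class-c propensity ∝ `exp(c·δ/2·s_a)` with
`s_a = ±1`, `c = ±1`. Each peptide then draws its own composition from a
Dirichlet centred on the class propensity and samples residues i.i.d.;
lengths are uniform on 8–25.

Defaults and why:

* `n_pos = 394`, `n_neg = 848` — mirrors the published benchmark's
  imbalance so oversampling is exercised realistically.
* `delta = 0.6` — a moderate, learnable but imperfect signal; `delta = 0`
  makes the classes exchangeable (the null-calibration condition) and
  `delta = 2` is effectively saturating (the strong-signal condition used
  in the calibration tests).
* `concentration = 50` — within-class compositional dispersion comparable
  to the between-class shift at moderate δ, so peptides of the same class
  are similar but far from identical.

What this generator does *not* emulate: positional motifs, length–class
correlation, phylogenetic redundancy between peptides, or any real
MHC-binding biology. Passing tests therefore demonstrate that the pipeline
recovers compositional signal without leaking information — they say
nothing about accuracy on real IL-10 data, which depends on how much of
the true signal is compositional.

## Calibration checks and problem sizes

The test suite runs three end-to-end calibrations at the benchmark scale
(1242 peptides, AAC+DPC features): exchangeable classes must give
cross-validated AUC within 0.1 of 0.5; a strong signal (δ = 2) must give
cross-validated accuracy above 0.95 with the stack no more than 0.02 AUC
behind its best base learner across 5 held-out splits; and permuting the
labels of the strong-signal dataset must collapse accuracy to the
majority-class rate — a leak detector for the whole pipeline, since any
train/test contamination shows up as above-chance performance on permuted
labels. Unit-level checks use smaller simulations (tens to hundreds of
peptides) and exact brute-force oracles over a three-letter sub-alphabet.

## Known limitations

* The logistic meta-learner is unpenalised; with five well-behaved
  meta-features this is stable, but perfectly separable meta-features can
  produce the usual GLM separation warnings (suppressed, predictions
  clamped to [0, 1]).
* `class::knn` breaks distance ties at random internally; with continuous
  composition features exact ties are measure-zero, so refits remain
  reproducible in practice.
* ADASYN's neighbourhood census uses all classes while its interpolation
  pool is minority-only — the standard construction; with very small or
  fragmented minority classes (< k + 1 points) resampling refuses to run
  rather than extrapolate.
* Metrics are threshold-0.5 point estimates; threshold sweeps live only in
  the exported ROC points (`roc_points()`).
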