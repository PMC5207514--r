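---
title: "Methods: bi-profile Bayes SVM prediction of plant PTS1 proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bi-profile Bayes SVM prediction of plant PTS1 proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pts1pred)
```

## The prediction problem

PTS1-type peroxisomal proteins carry their targeting information at the
extreme C-terminus: a tripeptide signal (canonically SKL, with tolerated
variants such as ARL, SRL, SKM, PKL, SRM) recognised by the PEX5 receptor,
plus weaker positional preferences in the adjacent upstream sequence.
`pts1pred` models the last `L` residues of a protein — default `L = 30`,
positions labelled `-(L-1)…0` with 0 at the terminus — as the unit of
classification. Thirty residues is long enough to capture upstream
composition bias (observable out to roughly position −22 in curated plant
sets) while keeping the estimation problem tractable at typical training
sizes of a few hundred sequences; `length_sweep()` lets users revisit this
choice empirically on their own data.

## Windows and the alphabet

Sequences are cleaned to a 21-symbol alphabet: the 20 standard residues
plus `X`, which serves both as the map target for non-standard codes
(B, Z, J, U, O, gaps, internal stops) and as the left-pad for proteins
shorter than `L`. Padding rather than dropping short proteins is a
deliberate choice: a proteome scan must score every entry, and a padded
window still carries its genuine C-terminal signal. Pad symbols occupy
only the most-negative positions, so position 0 is always the true
terminus.

## Class-conditional profiles and the BPB encoding

For each class `c` (peroxisomal `c1`, non-peroxisomal `c-1`) the
position-specific occurrence of residue `a` at position `i` is estimated
as

$$P(a \mid i, c) = \frac{f_c(a, i) + \alpha}{m_c + 21\alpha}$$

with pseudocount `alpha = 1` (Laplace) by default. The smoothing is not
cosmetic: the classifier takes logarithms of these probabilities, and at
training sizes of ~90 sequences per class, zero counts are common at any
single position. `alpha = 0` remains available for descriptive use
(composition matrices, logos) and is rejected with an informative error
if it reaches the log-odds path.

A window is encoded as the **bi-profile Bayes vector**: its per-position
probabilities under the positive profile (entries `1…L`, read in
position order `-(L-1)…0`) concatenated with those under the negative
profile (entries `L+1…2L`). Encoding against *both* classes is the point
of the construction — a residue that is merely rare everywhere is
distinguished from one that is rare in positives but common in
negatives.

## Two classifiers

**Naive-Bayes log-odds.** Under positional independence the log
posterior odds reduce to
$\sum_i [\log P(s_i|c_1) - \log P(s_i|c_{-1})] + \log P(c_1)/P(c_{-1})$,
with the decision by sign and an exact tie (score 0) called negative —
the conservative direction for a screening tool. Class priors default to
the empirical class frequencies because they appear in the posterior;
a `priors = "uniform"` option exists because the conventional 1:2
positive:negative training ratio is a sampling artifact, not an estimate
of prevalence. Natural logarithms throughout; only sign and ordering
matter.

**BPB-SVM.** The primary classifier is a soft-margin SVM
(`e1071`/libsvm) on the BPB vectors, RBF kernel by default (linear and
polynomial available). Features already live in `(0, 1]`, so inputs are
not rescaled; this keeps the model self-contained and reproducible.
Defaults are `cost = 1` and `gamma = 1/(2L)` (one over the feature
dimension); `tune_pts1_svm()` selects them by stratified 5-fold
cross-validation over the conventional powers-of-two grids
`C ∈ 2^{-5,-3,…,15}`, `γ ∈ 2^{-15,-13,…,3}`, maximising pooled accuracy
at cut-off 0, with ties broken toward the smaller `C` then the smaller
`γ` (prefer the smoother model). Decision values are reported raw —
typically within about −3…3 for tuned fits, but never clipped — and a
query is called positive when its value is `≥` the cut-off (ties
inclusive). Cut-off 1.0 is the conventional default operating point;
1.5 trades sensitivity for the high specificity wanted in
whole-proteome scans. No class weighting is applied by default despite
the 1:2 imbalance (an option exposes it), and no probability
calibration is attempted. libsvm's decision-value orientation depends on
class order, so the fit stores an explicit sign convention checked
against the training data.

## Evaluation harness

Cross-validation uses stratified random folds (deterministic given the
seed); stratification prevents single-class folds at these class sizes.
Profiles and the SVM are refit inside each training fold — the encoding
is part of the model, and leaking test windows into the profiles would
bias results optimistically. Held-out confusions are **pooled** across
folds before computing Accuracy, Sensitivity, Specificity and MCC,
giving a single confusion over the dataset rather than a mean of fold
metrics. Metrics print at 3 decimals, rounded half away from zero, to
match the conventions of published operating tables; an MCC whose
denominator contains a zero marginal is reported as `N.A.`, and
zero-denominator sensitivity or specificity yields `NA` rather than an
error. `reconstruct_confusion()` inverts printed rates back to integer
counts (round half away from zero), which is how the test suite verifies
published table cells against the metric formulas.

## The synthetic generator: what it emulates and what it does not

`generate_synthetic()` produces the two-class structure the method
assumes: positives end in a tripeptide drawn uniformly from the
canonical motif set and carry, with probability 0.5 per position, an
enriched residue at the upstream positions −22, −21, −20, −14, −6, −5,
−4; negatives are unbiased background, resampled at the terminus until
their final tripeptide falls outside the motif set. Defaults mirror a
curated Arabidopsis-scale study design: 90 positives vs 176 negatives
(~1:2), full sequence lengths uniform on 50–500 residues. The background
is uniform over the 20 residues by default so the null is exactly known
in tests (a natural-composition option exists); the enrichment weight
0.5 makes the planted bias clearly visible above sampling noise at
n = 90, comparable to a strong logo signal.

Two features of real data are deliberately **not** emulated, and they
bound what passing tests show. First, real negatives can end in
PTS1-like tripeptides without being peroxisomal — that is why the
problem is hard — whereas generated classes are exactly separable at the
terminus by construction, so the synthetic signal is cleaner than
reality. In particular, grid search on separable synthetic data
frequently ties at pooled accuracy 1.0, and the smaller-C tie-break then
yields compressed decision values at which the 1.0 cut-off is extremely
conservative; published mid-0.9 sensitivity at that cut-off reflects
non-separable real training sets and is not generally reproduced by the
stand-in. Second, real sequences share phylogenetic correlation
(homology), which the generator's i.i.d. draws lack; the package's
greedy redundancy filter — keep a record only if its C-terminal-window
identity to every kept record is below the threshold, visiting records
in input order — is a documented, reproducible stand-in for
alignment-and-clustering redundancy removal, not a re-implementation of
it.

## Numerical and degenerate-input choices

* Profile rows are validated to sum to 1 within 1e-9; the naive-Bayes
  score is checked against a direct product-of-probabilities oracle to
  1e-9 on toy alphabets.
* Composition matrices exclude pads from each position's denominator; a
  position that is all pad is flagged and reported `NA`.
* Positional contrast uses total-variation distance
  (`½ Σ|p − q|` per position): bounded in `[0, 1]`, symmetric, and zero
  exactly at equality — a transparent operationalisation of "how
  different are two logos here".
* Model archives are versioned; loading checks a magic tag and format
  version, and a save/load round trip reproduces decision values
  bit-for-bit.
* Duplicate FASTA ids are deduplicated with a suffix and a warning;
  empty files and sequences that clean to nothing are errors.

## Problem sizes used by the test suite

Unit and property tests run on small generated cohorts (tens of
sequences, window lengths 3–30) and on study-size cohorts of 90/176 and
99/196; the hyperparameter grid is exercised in full (110 cells × 5
folds) where the selection procedure itself is under test, and on
reduced grids elsewhere. These sizes keep the whole suite under half a
minute while covering every code path at realistic dimensions.

## Known limitations

* The SVM backend is libsvm; other conformant backends would differ in
  optimizer internals, so decision values are reproducible within this
  package but not bit-comparable across SVM implementations.
* Scores are uncalibrated margins, not probabilities.
* The generator's independence and separability assumptions make
  synthetic benchmarks optimistic; conclusions about real proteomes
  require curated training data.
* Dipeptide or higher-order features, position weighting, and ROC-based
  cut-off selection are out of scope.
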