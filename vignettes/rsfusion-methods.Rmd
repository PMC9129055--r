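---
title: "Resting-state activity measures and fused classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state activity measures and fused classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfusion)
```

This vignette is the package's account of its methods: the models behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic cohorts do and do not emulate, and the numerical
conventions that matter when you compare output against other software.

## The pipeline at a glance

A subject enters as a 4D BOLD array with voxel geometry and repetition
time TR. Per subject the pipeline computes up to four voxel-wise activity
maps, vectorises them over a brain mask into a feature matrix, ranks and
selects features on training subjects, trains a soft-margin linear SVM,
and evaluates by repeated stratified nested cross-validation, with either
decision-level (majority-vote) or feature-level (concatenation) fusion
across measures.

## Temporal preprocessing

Spatial preprocessing (slice timing, motion correction, normalisation to a
common grid) is out of scope: the package assumes already-aligned grids.
Three temporal/spatial-smoothing steps are provided:

- **Linear detrend** — per in-mask voxel, the least-squares line in time is
  removed. Exact for affine series; idempotent.
- **Ideal bandpass** — a rectangular discrete-Fourier filter: bins with
  `low_hz ≤ f ≤ high_hz` (default 0.01–0.1 Hz) are retained, all others
  including DC are zeroed. An ideal filter (rather than, say, a Butterworth
  design) keeps in-band tones bit-exact and out-of-band rejection total,
  which makes spectral measures analytically checkable. Bin-edge ties are
  stabilised with a 1e-12 tolerance.
- **Gaussian smoothing** — separable convolution with per-axis standard
  deviation `fwhm_mm / (2√(2 ln 2)) / voxel_size_mm[axis]` (0.566 voxels at
  FWHM 4 mm on 3 mm voxels). Convolution is mask-renormalised (the masked
  map is convolved and divided by the convolved mask), so constants are
  preserved exactly for any mask and values near mask borders are not
  dimmed.

**Order of application.** ALFF and fALFF are computed on detrended-only
series: bandpassing to 0.01–0.1 Hz first would make fALFF identically 1,
since its denominator is the full spectrum. ReHo and VMHC are computed on
detrended-and-bandpassed series. Maps are z-scored per subject over the
mask, then the ALFF, fALFF and ReHo maps are smoothed (FWHM 4 mm); VMHC is
left unsmoothed, since its Fisher-z values are already a cross-voxel
statistic of smooth series.

## The four measures

**ALFF** is the mean of the one-sided amplitude spectrum 2|X(f)|/T over
in-band bins. "Amplitude" (not squared power) is the convention of the ALFF
literature; `type = "power"` switches to mean squared amplitude if a power
reading is wanted.

**fALFF** is the in-band amplitude sum divided by the amplitude sum over
all positive frequencies up to Nyquist; it lies in [0, 1] and 0/0 is
defined as 0 (a flagged degenerate voxel).

**ReHo** is Kendall's coefficient of concordance among the K ≤ 27 series of
the 3×3×3 cube centred on the voxel:
W = 12 Σₜ (Rₜ − R̄)² / (K²(T³ − T)), with Rₜ the rank sum at time t and
R̄ = K(T+1)/2. Ranks use the average-rank convention and no tie correction:
continuous BOLD values make ties measure-zero. Mask-edge voxels use their
available K < 27 neighbours rather than being dropped; isolated voxels
(K < 2) get 0 and are flagged.

**VMHC** mirrors voxel (x, y, z) to (X+1−x, y, z) along the first axis and
stores atanh(r) with r clipped to ±(1 − 1e-7) so perfectly correlated pairs
stay finite. Midline (self-mirrored) voxels, voxels with out-of-mask
mirrors, and zero-variance series yield 0 and are flagged. The grid is
assumed left-right symmetric — true by construction for synthetic cohorts;
real data would need a symmetric template upstream.

Per-subject standardisation uses the population (1/N) standard deviation;
this matters only to exact-value tests, not to anything downstream.

## Feature selection

Feature matrices hold subjects × in-mask-voxel values, one block per
measure, with per-feature provenance (measure, voxel). Requesting several
measures *is* feature-level fusion. All rankers standardise features with
training statistics and break score ties by ascending feature index, so
results are deterministic and invariant to column order.

**FSV** (feature selection via concave minimisation) solves

$$\min_{w,\gamma,y,z,v}\;(1-\lambda)\Big(\tfrac{e'y}{m_1}+\tfrac{e'z}{m_2}\Big)
  + \lambda \sum_j \big(1 - e^{-\alpha v_j}\big)$$

subject to the linear class-separation constraints with slacks y, z ≥ 0 and
the envelope −v ≤ w ≤ v, via successive linearisation: each round replaces
the concave term with its gradient at the previous iterate and solves the
resulting LP. Two numerical choices matter:

- the **first round uses a near-zero gradient** (the slack-only robust
  separation LP). Starting the linearisation at v = 0 with the canonical
  λ = 0.5, α = 5 makes the all-zero solution a fixed point — the gradient
  λα there outweighs any slack reduction — and the method would return no
  ranking at all;
- defaults λ = 0.5, α = 5, tol = 1e-6, max 50 rounds are the method's
  standard settings; λ trades slack against support size, and the support
  is non-increasing in λ.

FSV is a *minimal-support* method: if two features already separate the
classes it will zero a third, informative or not. Its tests therefore plant
complementary features (each informative for a different third of the
patients) so that the true support is genuinely required. The LP backend is
a dense tableau simplex, practical up to a few dozen features; on full
maps, pre-reduce with a univariate ranker first. For that reason
`nested_cv()` defaults to the Wilcoxon ranker, which is vectorised over
thousands of voxel features.

**L0 approximation**: train the linear SVM, multiply each feature's scale
by |w_j|, retrain, until scales stabilise (relative change < 1e-6); the
accumulated scales are the scores. **Relief**: min-max scale to [0, 1],
then for each subject add |x − miss| − |x − hit| using the nearest same- and
other-class subjects; all subjects are used by default, making the result
deterministic. **Wilcoxon**: two-sided rank-sum p per feature — exact via
the null rank-sum distribution when both groups have ≤ 10 subjects and no
ties, a tie-corrected, continuity-corrected normal approximation otherwise.

**Sequential forward selection** evaluates the top-k features for
k = 1..k_max with a caller-supplied (inner cross-validation) evaluator and
returns the *smallest* k attaining the maximum validation accuracy. k_max
is capped at min(feature count, 200); the package default of 20 suits
cohorts of tens of subjects, where selected counts beyond the subject count
only add variance.

## Classification and fusion

The classifier is the hinge-loss soft-margin linear SVM with C = 10
(exposed as a parameter), fitted with libsvm via e1071 on
training-standardised features at termination tolerance 1e-8. The model
stores the primal weights, offset, and the training standardisation; the
decision value is d(x) = w·x − γ and d ≥ 0 labels a patient (the d = 0 tie
is measure-zero and documented rather than consequential). Training is
deterministic: the problem is convex and the solver is seeded by nothing.

Decision fusion majority-votes exactly three single-measure classifiers
that share every fold assignment; three voters make ties impossible. For
ROC purposes the fused decision value is the mean of the three decision
values. Feature fusion concatenates measure blocks before selection, so
the selector sees all measures at once; duplicated provenance (fusing a
matrix with itself) is permitted with a warning.

## Evaluation battery

**Nested cross-validation** (default 5 repetitions × outer 10-fold ×
inner 10-fold, all stratified): per outer fold, ranking, forward selection
(driven by the inner folds) and standardisation use training subjects only
— the held-out fold influences nothing but its own confusion counts, a
property asserted programmatically in the tests by permuting held-out
labels. Stratification departs from plain random splitting deliberately:
at desk-scale n both classes must appear in every fold. Aggregation pools
confusion counts within a repetition, averages metrics across repetitions,
and reports the across-repetition standard deviation; the Wilson 95%
interval is computed on the pooled counts. Pooling-vs-averaging is a
documented switch of interpretation rather than code: per-fold metrics are
available from `tidy()`.

**5×2-cv paired t-test**: five repetitions of stratified 2-fold
cross-validation, both classifiers on identical folds. With accuracy
differences p_i^(j), the statistic is
t = p₁⁽¹⁾ / √(⅕ Σᵢ sᵢ²), sᵢ² = (pᵢ⁽¹⁾−p̄ᵢ)² + (pᵢ⁽²⁾−p̄ᵢ)², compared
two-sided against qt(0.975, 5) ≈ 2.57. Degenerate all-zero variances give
t = 0 (no difference) or ±∞ (flagged, rejected).

**ROC**: curves sweep the decision threshold; vertical averaging fixes a
false-positive-rate grid (101 points by default), reads each curve's
true-positive rate by step interpolation (last value carried forward,
upper corner at each riser), and averages. The step convention makes a
single curve's trapezoid AUC equal its empirical Mann–Whitney AUC, which
the tests cross-check against an independent implementation.

**Discriminative mapping**: pooled-variance two-sample t per voxel, BH
step-up FDR at q = 0.05, clusters as 26-connectivity components, peak =
max |t| per cluster. An optional `min_abs_t` pre-threshold reproduces
cluster-forming conventions but is off by default. On desk-scale grids,
run this on unstandardised maps when the planted effect occupies a
non-trivial fraction of the mask: per-subject z-scoring makes the
background compensate for the planted shift (at realistic scale, tens of
voxels among 271633, the compensation is negligible).

**Rician robustness**: per fold, rank/select/train once on clean data;
then for each σ corrupt only the held-out volumes with
√((v+n₁)² + n₂²), n₁, n₂ ~ N(0, σ²), re-extract their features and
re-apply the stored model. σ = 0 runs the identical code path with no
corruption, so it reproduces the clean evaluation bit for bit. σ is in the
intensity units of the volume; for synthetic cohorts that is the baseline
noise standard deviation (1), the only scale available since magnitude-MRI
intensity units are arbitrary.

## The synthetic cohort generator

The generator defines the study conditions for every test: two groups on a
common grid, each voxel carrying independent Gaussian noise (sd 1) plus a
small common linear drift. Effect regions plant group differences per
measure family:

- *amplitude* (`alff`): a sum of five sinusoids with frequencies uniform in
  0.01–0.1 Hz and random phases, normalised to unit sd and scaled by the
  effect size, added to each region voxel — guaranteeing in-band energy so
  ALFF/fALFF responds;
- *coherence* (`reho`): one latent low-frequency series mixed into every
  region voxel with weight e as √(1−e²)·noise + e·latent, preserving the
  marginal variance while raising Kendall's W;
- *homotopy* (`vmhc`): a latent series mixed identically into each voxel
  and its x-mirror (the region must be mirror-closed).

Subject seeds are `spec_seed · 10⁶ + subject_index`, so any subject can be
regenerated in isolation and cohorts are bit-reproducible. Cohorts
round-trip through NIfTI-1 plus a `labels.csv` table.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: hemodynamic response shape, physiological
(cardiac/respiratory) noise, head motion, scanner drift beyond a linear
term, spatial autocorrelation of the noise, anatomy, and realistic
between-subject variability. The synthetic experiments validate the
*machinery* (measures respond to their own effect family, selection finds
planted voxels, fusion does not underperform its components, the protocol
leaks nothing); they do not predict accuracies on any real clinical
cohort.

## Problem sizes and runtime

Defaults target a desk scale chosen so the full pipeline runs in well under
two minutes on one CPU: grid 12×14×12 (or 12³ in the examples), T = 120,
TR = 2 s, 10 + 10 subjects. The test-suite experiments use 5-fold outer /
5-fold inner single-repetition cross-validation at that scale; the
full-size protocol (5 × 10-fold × 10-fold, 271633-voxel masks) is the same
code with larger arguments. Kendall's W over a 12³ grid with T = 100 takes
a few seconds per subject; everything else is fractions of a second.

## Known limitations

- FSV's LP backend is dense; at thousands of features use a univariate
  pre-reduction or a different ranker.
- VMHC requires a mirror-symmetric grid; there is no template
  symmetrisation.
- Decision fusion is defined for exactly three voters.
- The discriminative-map peak table reports voxel coordinates, not atlas
  labels.
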