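# rsfusion

Voxel-wise resting-state fMRI activity measures and fused linear-SVM
classification for two-group (patient vs control) studies, with a synthetic
4D BOLD cohort generator so the whole pipeline can be exercised, tested and
benchmarked without scanner data.

## What it does

Resting-state fMRI case-control studies commonly summarise each subject's 4D
BOLD recording into voxel-wise activity maps and classify subjects from
those maps. `rsfusion` implements that workflow end to end:

**Activity measures** (per subject, per voxel, over a brain mask):

- **ALFF** — amplitude of low-frequency fluctuations: the mean one-sided
  amplitude spectrum 2|X(f)|/T over 0.01 ≤ f ≤ 0.1 Hz;
- **fALFF** — fractional ALFF: in-band spectral mass divided by the total
  mass over 0 < f ≤ Nyquist (0.25 Hz at TR = 2 s);
- **ReHo** — regional homogeneity: Kendall's coefficient of concordance
  W = 12 Σₜ(Rₜ − R̄)² / (K²(T³ − T)) over the K ≤ 27 voxels of the 3×3×3
  neighbourhood;
- **VMHC** — voxel-mirrored homotopic connectivity: the Fisher z-transform
  atanh(r) of the Pearson correlation between a voxel and its left-right
  mirror.

Temporal preprocessing (linear detrend, ideal 0.01–0.1 Hz bandpass,
mask-renormalised Gaussian smoothing at FWHM 4 mm) is built in; spatial
preprocessing (motion correction, normalisation) is assumed done upstream.

**Feature selection** over subject × voxel feature matrices: feature
selection via concave minimisation (FSV, solved by successive linearisation
of linear programs), an L0-norm approximation by iterative classifier
rescaling, Relief, and the Wilcoxon rank-sum test — each producing a
ranking consumed by sequential forward selection driven by inner
cross-validation accuracy.

**Classification and fusion**: soft-margin linear SVM (C = 10, patients on
the positive side of d(x) = w·x − γ), decision-level fusion by majority
vote over three single-measure classifiers, and feature-level fusion by
concatenating measure blocks before selection.

**Evaluation**: repeated stratified nested cross-validation (selection and
standardisation computed on training subjects only), accuracy / sensitivity
/ specificity with Wilson 95% intervals, the 5×2-cv paired t-test
(t compared against qt(0.975, 5) ≈ 2.57), vertically averaged ROC curves
with trapezoid AUC, voxel-wise two-sample-t discriminative maps with
Benjamini–Hochberg FDR control and cluster peaks, and a Rician-noise
(√((v+n₁)² + n₂²)) robustness protocol that corrupts only test volumes.

## Worked example

```r
library(rsfusion)

# a 10 + 10 synthetic cohort with planted amplitude, coherence and
# homotopic-correlation effects in patients
regions <- list(
  effect_region("alff", as.matrix(expand.grid(2:4, 2:4, 2:4)), 3, "patients"),
  effect_region("reho", as.matrix(expand.grid(8:10, 2:4, 8:10)), 0.8, "patients"),
  effect_region("vmhc", as.matrix(expand.grid(c(2, 11), 6:8, 6:8)), 0.8, "patients")
)
spec <- cohort_spec(n_patients = 10, n_controls = 10, grid = c(12, 12, 12),
                    n_timepoints = 100, effect_regions = regions, seed = 7)
cohort <- generate_cohort(spec)

mask <- full_mask(c(12, 12, 12))
maps <- cohort_activity_maps(cohort, c("alff", "reho", "vmhc"), mask)
fm <- maps_to_feature_matrix(maps, mask)
fm
#> <feature_matrix> 20 subjects (10 patients / 10 controls) x 5184 features

report <- nested_cv(fm, "single", n_rep = 1, n_outer = 5, n_inner = 5,
                    k_max = 10, seed = 3)
report
#> <cv_report> single scheme, 1 reps x 5 outer folds
#>   accuracy 0.950 [Wilson 95%: 0.764, 0.991], sensitivity 1.000, specificity 0.900, AUC 0.951
```

The report says that, across the five held-out folds, 19 of 20 subjects
were classified correctly (all 10 patients, 9 of 10 controls), with a
Wilson 95% interval of [0.76, 0.99] on the pooled proportion and a
vertically averaged AUC of 0.951. `tidy(report)` returns the per-fold
confusion counts, `report$folds$selected_features` the voxels each fold
selected, and `plot_cv_roc(report)` the averaged ROC curve.

Fusion uses the same interface: `nested_cv(list(fm_reho, fm_vmhc,
fm_falff), "decision", ...)` majority-votes three single-measure
classifiers, and `nested_cv(list_of_matrices, "feature", ...)` concatenates
the measures before selection.

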