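Package: rsfusion
Title: Resting-State fMRI Activity Measures with Fused Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise resting-state fMRI activity measures (ALFF, fALFF,
    ReHo via Kendall's coefficient of concordance, and voxel-mirrored
    homotopic connectivity), temporal preprocessing (linear detrending,
    ideal 0.01-0.1 Hz bandpass, mask-renormalised Gaussian smoothing),
    feature ranking by concave-minimisation feature selection (FSV),
    an L0-norm approximation, Relief and the Wilcoxon rank-sum test with
    sequential forward selection, soft-margin linear support-vector
    classification with decision-level (majority-vote) and feature-level
    (concatenation) fusion, and an evaluation battery: nested
    cross-validation, Wilson score intervals, the 5x2-cv paired t-test,
    vertically averaged ROC curves, voxel-wise discriminative mapping with
    false-discovery-rate control, and a Rician-noise robustness protocol.
    Includes a synthetic two-group 4D BOLD cohort generator with planted
    amplitude, local-coherence and homotopic-correlation group effects so
    the full pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
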