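Package: imu2grf
Title: Joint Angles and Vertical Ground Reaction Forces from Three
    Inertial Sensors During Running
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates sagittal lower-body joint angles and vertical ground
    reaction forces (vGRF) during running from a minimal wearable setup of
    three inertial measurement units (pelvis and both lower legs).  Two
    concatenated feed-forward neural networks are trained per subject or
    across subjects: the first maps pelvis-relative lower-leg orientations
    (quaternions) to hip, knee and ankle flexion/extension angles, the
    second maps those angles together with global-frame vertical sensor
    accelerations to per-foot vGRF in body weights.  The package includes a
    multi-subject synthetic treadmill-running simulator, signal
    preprocessing (zero-phase Butterworth force filtering, 120 Hz
    resampling, 20 N stance segmentation), continuous and discrete outcome
    metrics (stride-wise RMSE, Fisher-averaged correlation, peak vGRF,
    loading rate, maximal knee flexion in stance, Bland-Altman limits of
    agreement) and evaluation drivers for single-subject,
    leave-one-subject-out, feature-ablation and speed-generalization
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
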