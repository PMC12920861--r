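Package: vfpose
Title: Vocal-Fold Pose Estimation and Anterior Glottic Angle Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Keypoint-based vocal-fold pose estimation for laryngoscopy
    frames. Implements three-keypoint Gaussian heatmap regression with a
    channel-weighted mean-squared-error loss on a MobileNetV2 U-Net
    backbone (trained with a small built-in float32 network engine), the
    two standard comparison baselines (direct coordinate regression and
    glottal-triangle segmentation with minimum-enclosing-triangle
    decoding), anterior glottic angle (AGA) computation, COCO-keypoint
    dataset handling with patient-grouped cross-validation, a synthetic
    laryngoscopy frame generator with exactly known landmarks, and the
    repeated-measures evaluation statistics (RM-ANOVA, Holm-Bonferroni
    corrected paired comparisons, Hedges' g).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
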