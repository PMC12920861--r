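# vfpose

Vocal-fold pose estimation and anterior glottic angle (AGA) analysis for
laryngoscopy frames.

Assessing vocal-fold motility from videoendoscopy hinges on the anterior
glottic angle: the angle at the anterior commissure `A` between the two
vocal-fold free borders, whose posterior endpoints are the keypoints `LV`
(left fold, image right under the endoscopic convention) and `RV`. Manual
frame marking is slow and rater-dependent. `vfpose` implements a
keypoint-based estimation pipeline for clinicians and medical-imaging
researchers:

* **Gaussian heatmap regression** of the three keypoints — each landmark is
  supervised as a full-grid Gaussian `exp(-((x-x_c)^2+(y-y_c)^2)/(2σ^2))`
  with σ = 20 px at 224×224 — on a MobileNetV2 U-Net (17 inverted residual
  blocks, four skip-connected decoder blocks), trained with a
  channel-weighted MSE, `L = Σ_c w_c · (1/N) Σ_j (pred − true)²`, with
  weights (1.2, 1.2, 1.0) for (LV, RV, A). The network engine (float32
  forward/backward, Adam) is built into the package — no external deep
  learning framework.
* The two standard **baselines**: direct coordinate regression (separable
  convolution head) and glottal-triangle segmentation with soft Dice loss,
  decoded through the **minimum enclosing triangle** of the predicted
  mask.
* AGA computation, `AGA = |atan2(u×v, u·v)|` for `u = LV−A`, `v = RV−A`.
* COCO-keypoint dataset I/O, preprocessing, on-the-fly augmentation and
  **patient-grouped k-fold cross-validation**.
* A **synthetic laryngoscopy generator** with exactly known landmarks
  (log-normal AGA population with median 15.12°, oncologic occlusions,
  white-light and narrow-band palettes) so the whole pipeline is testable
  without clinical data.
* The comparison statistics used by the original study of this method:
  repeated-measures ANOVA over folds, Holm–Bonferroni-corrected paired
  t-tests, and Hedges' g — plus the study's per-fold result tables as a
  plain-text fixture, so every published cross-fold aggregate is
  recomputable in under a second.

## Worked example

Train the heatmap model on synthetic frames and estimate angles:

```r
library(vfpose)

cfg <- synth_config(n_patients = 30, width = 224, height = 224, seed = 7)
ds  <- generate_dataset(cfg)
folds <- make_patient_folds(ds$records, k = 5, seed = 1)
fid <- vapply(ds$records, function(r) r$frame_id, character(1))

fit <- vf_train(ds$records[fid %in% folds[[1]]$train_ids],
                ds$records[fid %in% folds[[1]]$val_ids],
                model_config("heatmap", input_size = 224, width = 0.5),
                train_config(max_epochs = 8, patience = 5,
                             learning_rate = 3e-3, augment = FALSE))
print(fit)
#> Vocal-fold pose network (heatmap variant)
#>   input 224x224, width 0.50, 1,030,443 parameters
#>   trained 8 epochs (best epoch 7, val loss 0.01127)

test <- ds$records[fid %in% folds[[1]]$test_ids]
pred <- predict(fit, test)
mean(mapply(function(p, r) mean(keypoint_error(p, r$triplet)),
            pred$triplets, test))
#> [1] 3.162366                # mean keypoint error, pixels in 224-space

compute_aga(pred$triplets[[1]])        # predicted angle, degrees
#> [1] 34.50464
compute_aga(test[[1]]$triplet)         # ground truth
#> [1] 35.58774
```

The printed numbers mean: after eight epochs on ~70 synthetic training
frames the network localizes the three landmarks to ~3 px on
held-out patients, and the AGA derived from the predicted keypoints is
within a fraction of a degree of the constructed truth for this frame.

Verify the full statistics layer against the study's published per-fold
tables (no training involved):

```r
v <- verify_reference_aggregates()
attr(v, "all_pass")
#> [1] TRUE
head(v, 3)
#>                quantity computed reported   tol pass
#> 1    rmse_px_lv_heatmap   5.0920     5.09 0.005 TRUE
#> 2     rmse_px_a_heatmap   6.5600     6.56 0.005 TRUE
#> 3    rmse_px_rv_heatmap   6.4040     6.40 0.005 TRUE
```

A thin command-line wrapper is available as `scripts/vfpose`
(`synth | run | tables | report`).

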