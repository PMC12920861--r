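---
title: "Vocal-fold pose estimation: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vocal-fold pose estimation: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Vocal-fold (VF) motility is assessed in videoendoscopy through the anterior
glottic angle (AGA): the angle at the anterior commissure (`A`) between the
two vocal-fold free borders. Manual marking of laryngoscopy frames is slow
and rater-dependent, so the package estimates the three anatomical
keypoints — the posterior angles of the left and right vocal fold (`LV`,
`RV`) and the anterior commissure (`A`) — directly from a frame and derives
the AGA from them.

With \(u = LV - A\) and \(v = RV - A\),

\[ \mathrm{AGA} = \left| \operatorname{atan2}(u_x v_y - u_y v_x,\; u_x v_x + u_y v_y) \right| \]

reported in degrees in \([0, 180]\). The two-argument arctangent form is
numerically robust near collinearity; the magnitude is taken because the
clinical quantity is unsigned. Coordinates are 0-based pixel centers, x
rightward, y downward; with that orientation the cross product
\((LV-A)\times(RV-A)\) is positive when `LV` lies on the image right, which
is the anatomical left under the endoscopic viewing convention. Degenerate
triplets (a keypoint coinciding with `A`) raise an error rather than
returning NaN; downstream evaluation treats such predictions as
infeasible-AGA cases and excludes them with a count.

## Three estimation approaches

All three share a MobileNetV2 encoder: an initial 3x3 stride-2 convolution
with 32 filters, then 17 inverted residual blocks (expansion factor 6
except the first, expansion widths growing from 32 to 576 at width
multiplier 1). The variants differ in the head:

* **Heatmap regression** (the primary approach): a U-Net decoder of four
  blocks, each upsampling by 2, concatenating the resolution-matched
  encoder feature map, and applying two 3x3 conv + batch-norm + ReLU
  layers; then a head of three 3x3 convolutions (first two ReLU, last
  sigmoid) at the input resolution, one channel per keypoint. Keypoints
  are decoded as the per-channel argmax (ties broken in row-major order,
  first occurrence; no sub-pixel refinement).
* **Direct regression**: the encoder followed by two separable
  convolutions (depthwise + pointwise), global average pooling and a
  6-value sigmoid head for the normalized coordinates
  \(x/(S-1), y/(S-1)\). Trained with coordinate MSE.
* **Glottal segmentation**: the heatmap architecture with a single
  sigmoid channel, trained with soft Dice loss against the filled
  triangle `LV`–`A`–`RV`. At inference the probability map is thresholded
  at 0.5 and keypoints are recovered as the vertices of the minimum
  enclosing triangle of the predicted mask.

### Ground-truth heatmaps

Channel \(c\) holds an unnormalized Gaussian
\(\exp(-((x-x_c)^2 + (y-y_c)^2)/(2\sigma^2))\) with \(\sigma = 20\) px at
the 224x224 working resolution, evaluated over the full grid without
truncation or renormalization, so the peak value is exactly 1 at the pixel
nearest the keypoint. For other input sizes the default \(\sigma\) scales
proportionally (`20 * input_size / 224`). Occluded keypoints (COCO
visibility 1) receive a standard Gaussian and full loss weight; absent
keypoints (visibility 0) are rejected at load time by default.

### Losses

The primary loss is the channel-weighted MSE
\(\mathcal{L} = \sum_c w_c \frac{1}{N}\sum_j (p_{jc} - t_{jc})^2\) with
\(N\) the per-channel pixel count (batched training averages over batch x
pixels per channel before the weighted channel sum). The weights are
\(w_{LV} = w_{RV} = 1.2\), \(w_A = 1.0\), emphasizing the free-border
landmarks. Ablation losses: plain MSE, and a weighted l1 whose elementwise
weight is `w_hi` where the target exceeds a threshold and `w_lo` elsewhere
(the published description leaves the threshold and weights unstated;
the defaults 0.5 / 2 / 1 are placeholders for the ablation hook, not
calibrated values). Segmentation uses soft Dice
\(1 - 2\sum pt / (\sum p + \sum t + \varepsilon)\) with
\(\varepsilon = 10^{-7}\) guarding empty masks; on binarized inputs it
reduces to the counting form \(1 - 2TP/(2TP+FP+FN)\).

## The network engine

No deep-learning framework is used: the package contains a compact float32
engine (RcppArmadillo) with im2col+GEMM 3x3 convolutions, direct depthwise
convolutions, batch normalization, ReLU6/ReLU/sigmoid, nearest-neighbour
upsampling, concatenation, residual addition, global average pooling, and
hand-derived backpropagation with Adam (lr 0.001 default, \(\beta\) =
0.9/0.999). Design choices that matter:

* **Batch norm**: batch statistics over batch x spatial per channel during
  training, running averages (momentum 0.1) at inference, epsilon `1e-3`
  (the Keras convention for this architecture; the larger epsilon also
  conditions float32 training better than `1e-5`).
* **Skip taps**: the encoder's last feature map at output strides 2, 4, 8
  and 16 feeds the four decoder concatenations; the bottleneck is at
  stride 32. Decoder widths halve per block (256, 128, 64, 32 at width 1,
  scaled by the multiplier and rounded to multiples of 8), a monotone
  scheme ending in a 16-channel head.
* **Head bias**: the final convolution's bias is initialized to -3 so the
  initial sigmoid output (~0.05) matches the mostly-background targets;
  this removes several epochs otherwise spent suppressing background.
* **Width multiplier**: `width < 1` shrinks every channel count (multiples
  of 8, minimum 8), giving desk-scale networks with the identical
  topology; `width = 1` reproduces the published 32-to-576 progression
  (4.0M parameters for the heatmap variant; the encoder alone, 1.81M,
  matches the published MobileNetV2 backbone size).
* **Gradient verification**: backprop is checked against central finite
  differences on the BN-free head layers (float32 plus batch-norm variance
  terms make finite differences unreliable for deep parameters; the
  chain is additionally covered by the exact wmse-vs-mse gradient-scale
  identity and by convergence tests).
* **Pretrained encoder weights are off by default** and can only be
  supplied explicitly (`init_state`); published results used ImageNet
  pretraining, which is a documented fidelity gap of the default
  configuration.

## Data handling

Frames are read from COCO Keypoint JSON (category keypoints `LV`, `RV`,
`A`, flat `[x, y, v]` triples) with patient, pathology and modality
carried as image-level fields. Preprocessing resizes 640x480 frames
anisotropically to 224x224 (aspect ratio is deliberately not preserved;
all pixel errors live in the 224 space), scales keypoints by the same
factors (`x * 224/width`), maps intensities to [0, 1] and removes the
per-frame per-channel mean.

Training augmentation applies, each independently with probability 0.5:
horizontal flip, vertical flip, rotation about the image center uniform in
±30°, brightness shift in ±0.1, hue rotation in ±0.2 (of the hue wheel)
and saturation scaling in [0.5, 1.5]. Two subtleties are easy to get
wrong: a horizontal flip reverses anatomical left/right, so the LV and RV
labels must swap (and when a heatmap stack itself is flipped, its first
two channels must swap accordingly — `swap_channels_on_hflip`); and a
rotation that would push a keypoint outside the frame is resampled up to
five times, then skipped. Color jitter operates on the [0, 1] image before
mean removal.

Cross-validation is patient-grouped: patients are shuffled under a seed
and partitioned into k near-equal test groups; within each fold 20% of the
remaining patients are held out as the validation set for early stopping
(the published protocol monitors a validation loss but does not describe
the validation split; the 20% patient-grouped convention is this
package's choice). Training follows the published protocol: Adam at 0.001,
batch size 8, at most 200 epochs, early stopping after 10 epochs without
validation improvement, best-validation checkpointing, all seeded.

## Decoding masks: minimum enclosing triangle

The segmentation baseline needs the smallest-area triangle containing
every foreground pixel center. The implementation takes the convex hull,
enumerates candidate triangles whose three sides are flush with hull edges
(all edge-normal triples, using support functions), and refines the best
candidate by Nelder-Mead over the three supporting-line orientations. The
refinement step covers optimal triangles that are flush on fewer than
three sides; tests verify the result against an independent brute force
(flush-edge theorem plus two-angle grid search) to within 0.5% in area.
Vertices are then labeled: the glottal triangle is elongated with its apex
at the anterior commissure, so the vertex with the smallest interior angle
becomes `A` (this assignment rule is a package convention — the published
description does not state one), and LV/RV are assigned by the orientation
convention above; an equilateral tie resolves to the lowest y, then lowest
x. Masks that are empty, smaller than three pixels or collinear are
undecodable: the frame is excluded from per-image metrics with a logged
count, mirroring the infeasible-AGA cases reported for this baseline.

## Synthetic laryngoscopy frames

The generator exists so every stage is testable with exactly known
landmarks. Per patient it draws a shared anatomy — apex position, fold
length, band width, midline direction, tissue tint, modality (30%
narrow-band by default; the published modality mix is not stated), and an
oncologic flag at rate 28/124 — and 1-5 frames (probabilities 0.10, 0.15,
0.25, 0.25, 0.25: median 3, mean 3.4, reproducing both the published
median and, over 124 patients, a plausible dataset size of roughly 420
frames). The per-patient AGA follows a log-normal fitted to the published
summary statistics (median 15.12°, quartiles 8.09° and 22.19° give sdlog
0.748), clipped to the observed range [1.32°, 91.85°]; per-frame angles
jitter around the patient's base angle (sdlog 0.10). Frames render a dark
rounded lumen, two bright fold bands meeting at `A`, and a dark triangular
glottal gap whose vertices are exactly the keypoints, then add an
illumination gradient, specular spots, Gaussian noise, occasional motion
blur, and — for oncologic patients — a bright occluding mass near the
anterior commissure (the occlusion model is an invention motivated by the
reported error concentration at that landmark; at desk scale it does not
measurably degrade apex localization — the trained network still finds the
dark gap apex — so the clinically observed oncologic error inflation is
not reproduced by this simple occlusion model). All draws run through the
R RNG under the configuration seed, so a dataset is a pure function of its
configuration.

What the generator does **not** emulate: real tissue texture and color
variability, camera optics and lens distortion, temporal correlation
within a video, annotation noise, and anatomy beyond the glottal triangle.
Passing the recovery tests therefore demonstrates that the estimation
machinery works end to end on images with the right coarse structure; it
does not certify clinical accuracy.

## Evaluation and statistics

Per-keypoint error is \(\sqrt{(\Delta x^2 + \Delta y^2)/2}\) — the RMSE
over the two coordinates of one keypoint, which is the Euclidean distance
divided by \(\sqrt 2\). The published image-level "RMSE" admits either
reading; this convention is fixed because it reproduces the published
cross-fold aggregates, and it is isolated in `keypoint_error()`. AGA error
is plain MAE/RMSE over test frames in degrees. Fold summaries are mean ±
SD over a fold's test images; cross-fold aggregates are unweighted means
of the five fold means, and the overall pixel error is the mean of the
three keypoint aggregates.

Method comparison uses one-way repeated-measures ANOVA with folds as
subjects: \(F = MS_{method}/MS_{residual}\) with \((m-1, (m-1)(n-1))\)
degrees of freedom, and classic \(\eta^2 = SS_{method}/SS_{total}\) — this
convention reproduces two of the three published effect sizes (0.632,
0.399); the third published value (0.50 for the pixel-RMSE ANOVA) is not
reproducible under any standard convention we tested (classic \(\eta^2\)
gives 0.600) and is excluded from verification. Post hoc comparisons are
paired t-tests on fold-level values with Holm-Bonferroni adjustment, and
Hedges' g uses the two-sample pooled SD
\(\sqrt{(s_a^2+s_b^2)/2}\) with bias correction \(J = 1 - 3/(4\,df-1)\),
\(df = 2n-2\) — fixed by reverse-verification against the published 2.76
and 1.20. Effect sizes are verified as magnitudes because the published
comparison directions are not in a consistent order. Published ±SD values
in the running text do not match across-fold SDs of the table cells under
either SD convention and are not verified; the published segmentation
degradation of 9.95 px is likewise inconsistent with the table it
summarizes (the cells give ≈1.47 px) and is not verified.

The per-fold table cells of the original study ship as a plain-text
fixture, so `verify_reference_aggregates()` recomputes every cross-fold
mean, F, p, \(\eta^2\), Holm-adjusted p and Hedges' g and checks them at
printed precision without any training.

## Desk-scale study conditions

The parameter-recovery study runs width-0.5 networks at 224x224 on 200
synthetic frames (160 training, 40 validation, patient-grouped) with 50
held-out test frames, using a compact protocol: 3 epochs of Adam at 0.003
without augmentation. The synthetic task is high-contrast and converges in
two to three epochs under this protocol (the heatmap variant reaches
roughly 3-7 px mean keypoint error depending on the seed, against 10-15 px
for direct regression; the published clinical protocol of 200 epochs at
0.001 with augmentation is the package default for real training runs).
These sizes keep the whole suite at a few minutes per trained network on a
single CPU core. The direction of the published comparison — heatmap
regression beating direct coordinate regression — is checked across five
seeds at these conditions.

## Known limitations

* The engine is CPU-only and single-threaded; full-width training on a
  clinical-scale dataset is possible but slow.
* No ImageNet pretraining by default (weights cannot be bundled), so
  absolute errors on hard real-world data will exceed the published
  clinical numbers.
* The minimum-enclosing-triangle decoder assumes a roughly triangular
  glottal gap; non-triangular or multi-component masks decode poorly (by
  design — the study's annotation model is a triangle).
* Sphericity corrections (e.g. Greenhouse-Geisser) are deliberately not
  applied; the comparison machinery mirrors the plain RM-ANOVA that the
  reference results use.
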