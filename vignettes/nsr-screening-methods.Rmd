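---
title: "Methods: device-independent NSR quantification and screening"
author: "NSRscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: device-independent NSR quantification and screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Topical methyl nicotinate (AMN) elicits a local skin-flushing response
(NSR) that is attenuated and delayed in several psychiatric disorders —
depression (DP), bipolar disorder (BP) and schizophrenia (SZ) — relative to
healthy controls (HC). Clinically the response has long been graded on a
manual 4-point scale (0 = no erythema, 1 = incomplete, 2 = complete within
the patch area, 3 = spreading beyond it), which is subjective and
device-dependent: the apparent size and colour of the erythema change with
the camera, the lighting and the camera-to-arm distance.

`NSRscreen` implements an objective alternative. A patch with four 1
cm holes delivers AMN at 0.1, 0.01, 0.001 and 0.0001 M; photographs
of the forearm are taken 1, 5, 10, 15 and 20 minutes after application. A
printed label affixed to the arm serves two calibration purposes at once:
its white section is a known-white reference for colour correction, and its
known physical size anchors the pixel scale. The pipeline is then:

1. **Calibrate** each photograph (white balance, scale, resize to the
   128 x 512 model grid).
2. **Segment** the flushing area with an encoder--decoder network.
3. **Quantify** each application site as a normalized area
   `A_norm = A_detected / A_label` and, optionally, an objective 3-scale
   score.
4. **Classify** participants (HC vs. one disorder) from 20-dimensional
   concentration-by-time feature vectors with a SMOTE-balanced,
   grid-searched kernel SVM under stratified 5-fold cross-validation.

Because `A_norm` is a ratio of two areas measured on the same calibrated
grid, it is invariant to resolution and camera distance — the property that
makes the statistic device-independent.

# Calibration

**White balance.** The perfect-reflector method scales each channel by
`255 / mean(channel over the white patch)`. The *mean* (rather than the
max) is the white estimate because it is robust to specular highlights and
sensor noise; the choice of estimator is ours, as only the method family is
standard. When no explicit white-reference region is supplied,
`whiteRefFromLabel()` takes the brightest connected subregion of the label
mask (within 8% of its peak luminance). White balance is idempotent up to
rounding on unsaturated references; when noise pushes corrected patch
pixels past 255, clipping admits a residual of roughly one intensity level.

**Scale.** `calibrateScale()` rescales the image by
`targetLabelPx / measuredLabelPx`, where the measured size is the label
mask's bounding-box major axis (the absolute physical label size is not
needed — only relative normalization matters, and only a relative
calibration is possible without it). The default target of 120 px places
the four sites comfortably along the 512 px axis. Masks travel through the
same transform with nearest-neighbour interpolation so they stay boolean;
images are interpolated bilinearly.

**Augmentation.** During segmentation training each sample may pass through
one random geometric transform (rotation +/-15 degrees, shift +/-5%, scale
0.9--1.1, horizontal/vertical flips) applied identically to image and mask,
plus image-only photometric jitter (+/-20% brightness/contrast/saturation).
These magnitudes are mild defaults of ours; only the transform families are
prescribed. Flips are exact array reversals, so involution and
alignment properties hold bit-exactly.

# Segmentation

The segmenter is a plain U-Net, written for the CPU: `encoderDepth` stages
of two 3 x 3 ReLU convolutions and 2 x 2 max-pooling, a bottleneck,
mirrored decoder stages with nearest-neighbour upsampling and skip
concatenation, and a 1 x 1 sigmoid head. Convolutions are im2col + GEMM;
the backward pass is analytic and verified against numerical gradients in
the test suite. A pluggable pretrained encoder is deliberately out of
scope: one adequately trained segmenter suffices for the pipeline, and
bundling pretrained backbones would break the self-contained build.

Training minimises `BCE + (1 - softDice)` under Adam (lr `1e-3` default;
the examples in this package use `3e-3`, which converges faster on the
synthetic task). The BCE carries a per-image positive-class weight capped
at 10: flushing typically covers only a few percent of pixels, and without
the weight the optimiser can settle into an all-background state in which
the sigmoid saturates and the soft-dice gradient vanishes. The checkpoint
with the best validation Dice is kept; training aborts with a diagnostic on
a non-finite loss.

Data are split **by participant** (default 90/10/20 of 120, scaled
proportionally otherwise) so no person's images leak across sets. Dice and
IoU are computed per image and macro-averaged; an image with an empty
ground truth and an empty prediction scores 1, empty-vs-nonempty scores 0.
Probability maps are thresholded at 0.5 with `>=` counting as foreground,
and no morphological post-processing is applied — predictions are assessed
raw.

# Quantification and scoring

Detected flushing pixels are attributed to the four application sites by a
band partition: the application zone (columns 129--512 of the model grid by
default, i.e. everything right of the label) is split into four equal-width
bands ordered by descending concentration. The attribution rule is this
package's choice — the photographs' patch orientation fixes the ordering
but no published rule exists — so the geometry is configurable, and pixels
falling outside every band are counted and reported rather than silently
dropped.

`A_norm` feeds the objective 3-scale: score 0 below 0.1091, score 1 in
[0.1091, 0.1598), score 2 otherwise. The cut-points are midpoints between
the per-manual-score `A_norm` means of the reference distribution
statistics (`referenceScoreStats()`): the upper midpoint reproduces 0.1598
exactly, while the lower midpoint is 0.10915, which the published constant
truncates to 0.1091 — the package defaults keep the published constants
verbatim for bit-compatibility, and `deriveThresholds()` documents the
derivation. Manual scores 2 and 3 are merged (their reference means differ
by 0.0004): the "beyond the patch" criterion of score 3 is spatial, not
areal, and is not modelled here. The reference statistics are stored as
printed; their standard deviations are not exactly the square roots of the
printed variances, and we deliberately do not "repair" them.

Feature vectors flatten the 4 x 5 grid concentration-major (0.1 M block
first) with time ascending within each block; the ordering is recorded in
the row metadata of the resulting `NsrFeatureSet` (a
`SummarizedExperiment` with participants as columns).

# Screening

For each binary task (HC vs. one disorder) the harness runs stratified
5-fold cross-validation. Within each fold's 80% training portion:
features are standardized (fit on that portion only — unstated upstream,
but standard for SVMs, and toggleable), SMOTE balances the classes, and a
grid search selects the SVM hyperparameters by balanced accuracy using a
nested stratified 3-fold CV; the refit model predicts the untouched 20%.
Out-of-fold predictions from all folds are pooled into a single confusion
matrix — the only construction consistent with reported matrices whose row
sums equal the cohort sizes (60/20) — and all metrics derive from it.

SMOTE is implemented to its canonical definition (synthetic point
`x_i + u (x_nn - x_i)`, `u ~ U(0,1)`, `x_nn` among the k nearest minority
neighbours) rather than delegated, so its convexity property is directly
testable; it runs strictly inside training folds, and the test suite
asserts that perturbing a held-out sample cannot change its fold's selected
hyperparameters. The default grid (RBF: C in {0.1, 1, 10} x gamma in
{0.01, 0.1, 1}; polynomial: degree in {2, 3, 4}; SMOTE k in {3, 5, 7}) is
reverse-engineered from the reported winning parameter combinations, the
full searched grid being unpublished; ties resolve to the first listed
combination, making selection deterministic given the seed.

**Rounding of reported metrics.** Reported values round half-to-even on the
decimal value (`reportRound()`): 50/80 = 0.625 prints as 0.62 and
0.675 prints as 0.68. This is the only rule under which every published
metric reproduces from its confusion matrix; ordinary round-half-up fails
on 0.625. Sensitivity/specificity carry 4 decimals, other metrics 2.

Score-threshold baselines (`baselineScoreClassifier()`, `totalScore()`)
implement the classical single-concentration and total-score rules:
predict "patient" when the score falls below a cutoff, the attenuated
response being the disease signature.

# The synthetic generator

Every stage is testable without external data because the generator
emulates the study's structure: 60 HC + 3 x 20 patients, five time points,
four concentrations (600 image slots). True normalized areas follow
saturating growth
`a(t) = plateau * subj * (1 - exp(-rate * max(t - delay, 0))) * amp(conc)`
plus N(0, 0.03) measurement noise, clipped at zero. The functional form is
our choice; the constraints it encodes are the documented qualitative
findings: patients flush more slowly (median rate 0.16 vs 0.30 per min,
delay 2.5 vs 1 min) and lower (plateau 0.18 vs 0.21), amplitude decreases
with dilution and is near zero at 0.0001 M, where flushing is rarely
induced. Per-participant heterogeneity (log-normal susceptibility,
sd 0.35; log-normal rate factor, sd 0.35; delay jitter, sd 1 min) creates
the between-subject overlap that keeps the classification task statistical
rather than trivial: with the default "moderate effect", downstream
balanced accuracy lands in the 0.6--0.9 band across seeds, bracketing the
0.65--0.74 reported on real data. `effectSize = 0` equalises all groups
for null-calibration tests.

The renderer draws a forearm canvas (160 x 640 at distance 1), the label
with a white patch and dark ID marks, and one soft-edged erythema disc per
site whose pixel area equals `a_norm x label area`; it then applies a
per-device chromatic colour cast (diagonal RGB gains in [0.7, 1.3],
normalised to unit maximum — cameras auto-expose, and a super-unity gain
would saturate the white patch and destroy the information the white
balance needs), Gaussian blur, per-image camera distance in [0.85, 1.2],
and pixel noise. Ground-truth masks are fixed before cast, blur and noise,
mirroring annotation of the visible erythema.

What the renderer does **not** model: skin texture, hair, specular
highlights, irregular (non-elliptical) erythema, the spatial spread of
manual score 3, shadows, or perspective distortion. Passing tests therefore
demonstrate that the pipeline's machinery is correct and well-calibrated on
images with the assumed structure — not that the segmenter would reach the
same accuracy on real photographs, which require training-scale compute and
the external dataset.

# Numerical choices and problem sizes

* Segmentation tests train a depth-2, 8-channel U-Net. The overfit check
  uses 8 copies of one photograph for 35 epochs; the cohort-level check
  renders the default 120-participant cohort and trains on a 30-participant
  subset of the training split (times 1, 10 and 20 minutes) for 3 epochs,
  evaluating on all 100 test-split images. These sizes are chosen so the
  whole suite runs on a laptop-class CPU while the test split remains the
  full 20 participants.
* Weight init is He-scaled Gaussian, biases zero; a single run seed drives
  init, shuffling, augmentation draws, splits and SMOTE.
* Dice uses an additive smoothing constant of 1 in numerator and
  denominator.
* Statistical harness tests (permutation null, leakage, null effect) use a
  reduced RBF-only grid: they probe the protocol, not grid breadth.
* `calibrateScale` errors on labels under 9 px of area; `smoteOversample`
  requires `k < minority size` and suggests a smaller k otherwise;
  degenerate (zero-variance) features standardize to zero rather than NaN.

# Known limitations

* Only relative scale calibration is possible: the label's absolute
  physical size is carried as metadata but never printed on the images.
* The band partition assumes the four sites lie along the long axis right
  of the label; rotated or mirrored layouts need a custom `siteGeometry`.
* The manual 4-point scale's score 3 ("beyond the defined area") has no
  objective counterpart here; the 3-scale merges it with score 2.
* The U-Net is a compact CPU implementation intended for the calibrated
  512 x 128 inputs of this pipeline, not a general-purpose deep-learning
  framework; multiclass segmentation and GPU execution are out of scope.
* Binary HC-vs-disorder screening only; no 4-way classification, no
  probability calibration, and no EC50-based dose-response summary.
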