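# NSRscreen

Device-independent quantification of the niacin skin-flushing response
(NSR) from forearm photographs, and machine-learning screening of
psychiatric disorders built on it.

Topical methyl nicotinate elicits a skin-flushing (erythema) response that
is attenuated and delayed in depression (DP), bipolar disorder (BP) and
schizophrenia (SZ) relative to healthy controls (HC). A patch applies the
niacin ester at four dilutions (0.1–0.0001 M) through 1 cm holes and the
forearm is photographed 1, 5, 10, 15 and 20 minutes later, with a printed
label on the arm acting as both a white reference and a size fiducial.
`NSRscreen` turns those photographs into an objective screening measure:

* **Calibration** — perfect-reflector white balance against the label's
  white patch, fiducial-based scale normalization, resize to the 128×512
  model grid, and paired runtime augmentation for training.
* **Segmentation** — a compact CPU U-Net (Rcpp/Armadillo, dice+BCE loss,
  Adam) predicts the flushing mask; data are split *by participant*
  (90/10/20) and evaluated with macro-averaged Dice/IoU.
* **Quantification** — each application site becomes a normalized area
  `A_norm = A_detected / A_label`, quantized by the objective 3-scale
  (score 0 below 0.1091, score 1 in [0.1091, 0.1598), score 2 otherwise),
  and assembled into 20-dimensional concentration×time feature vectors
  (an `NsrFeatureSet`, a `SummarizedExperiment` subclass).
* **Screening** — stratified 5-fold cross-validated kernel SVM with SMOTE
  class balancing and grid search inside each fold, reported from the
  pooled out-of-fold confusion matrix (`ScreeningResult`).
* **Synthetic data** — a cohort and image generator emulating the open
  dataset layout (60 HC + 3×20 patients, 600 images), so the entire
  pipeline is testable offline.

## Worked example

Reported screening results can be recomputed from their confusion
matrices — here HC vs. DP with 3-scale features:

```r
library(NSRscreen)
m <- metricsFromConfusion(referenceConfusionMatrices("three_scale")[["HC vs DP"]])
reportRound(m$balancedAccuracy, 2)   # 0.74
reportRound(m$sensitivity, 4)        # 0.6
reportRound(m$specificity, 4)        # 0.8833
reportRound(m$overallAccuracy, 2)    # 0.81
```

Sensitivity 0.60 is the DP recall (12 of 20 patients caught), specificity
0.8833 the HC recall (53 of 60 controls cleared); balanced accuracy is
their mean, rounded as reported.

The same harness runs end-to-end on a synthetic cohort:

```r
fs  <- generateFeatureTable(cohortConfig(seed = 1), scheme = "three_scale")
res <- runScreening(fs, "HC vs DP", cv = cvConfig(seed = 1))
res
#> ScreeningResult: HC vs DP (three_scale features, 5-fold CV)
#>   pooled out-of-fold confusion (rows actual, cols predicted):
#>       predicted
#> actual HC DP
#>     HC 42 18
#>     DP  4 16
#>   balanced accuracy 0.75 | sensitivity 0.8000 | specificity 0.7000 | overall 0.72
```

The synthetic cohort's "moderate" group effect is calibrated so balanced
accuracy lands in the 0.6–0.9 band — bracketing what the measure achieves
on real data — rather than separating the groups trivially.

Image-level pieces follow the same pattern: `renderImage()` →
`preprocessImage()` → `trainSegmenter()`/`predictMask()` →
`quantifyImage()`. A thin command-line front end with `synth`, `ingest`,
`quantify` and `classify` subcommands lives in `inst/scripts/nsr-screen.R`.

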