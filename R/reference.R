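#' @include AllClasses.R
NULL

#' Reference per-score A_norm distribution statistics
#'
#' The normalized-area distribution statistics reported for the open NSR
#' dataset, per manual 4-point score: mean, variance and standard deviation
#' of A_norm among regions assigned each manual score. Stored verbatim as
#' published (the printed standard deviations are not exactly the square
#' roots of the printed variances, reflecting an unstated estimator detail
#' upstream; they are deliberately not recomputed here).
#'
#' @return data.frame with columns `score`, `mean`, `variance`, `sd`.
#' @export
#' @examples
#' referenceScoreStats()
referenceScoreStats <- function() {
  data.frame(score = 0:3,
             mean = c(0.0648, 0.1535, 0.1661, 0.1665),
             variance = c(0.0229, 0.0363, 0.0217, 0.0291),
             sd = c(0.1515, 0.1907, 0.1477, 0.1706))
}

#' Reference screening confusion matrices
#'
#' The pooled out-of-fold confusion matrices reported for SVM screening on
#' the open NSR dataset (60 healthy controls vs. 20 patients per disorder),
#' for both feature schemes. Rows are actual classes (HC first), columns
#' predicted. These serve as fixed inputs for recomputing the reported
#' performance metrics via [metricsFromConfusion()].
#'
#' @param scheme `"three_scale"` or `"direct_area"`.
#' @return named list of 2x2 matrices (`"HC vs BP"`, `"HC vs SZ"`,
#'   `"HC vs DP"`).
#' @export
#' @examples
#' metricsFromConfusion(referenceConfusionMatrices("three_scale")[["HC vs DP"]])
referenceConfusionMatrices <- function(scheme = c("three_scale",
                                                  "direct_area")) {
  scheme <- match.arg(scheme)
  mk <- function(hc1, hc2, p1, p2, patient) {
    m <- matrix(c(hc1, p1, hc2, p2), 2L, 2L,
                dimnames = list(actual = c("HC", patient),
                                predicted = c("HC", patient)))
    storage.mode(m) <- "integer"
    m
  }
  if (scheme == "three_scale")
    list("HC vs BP" = mk(45, 15, 8, 12, "BP"),
         "HC vs SZ" = mk(47, 13, 7, 13, "SZ"),
         "HC vs DP" = mk(53, 7, 8, 12, "DP"))
  else
    list("HC vs BP" = mk(41, 19, 7, 13, "BP"),
         "HC vs SZ" = mk(36, 24, 6, 14, "SZ"),
         "HC vs DP" = mk(33, 27, 5, 15, "DP"))
}
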