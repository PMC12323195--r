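#' @include utils.R
NULL

NSR_GROUPS <- c("HC", "DP", "BP", "SZ")
NSR_TIMES <- c(1L, 5L, 10L, 15L, 20L)
NSR_CONCENTRATIONS <- c(0.1, 0.01, 0.001, 0.0001)
MASK_KINDS <- c("flush", "label", "white_ref", "site")

#' NsrImage: a (possibly calibrated) NSR photograph
#'
#' Holds an RGB photograph of the niacin application zone on the forearm as a
#' `H x W x 3` numeric array with channel values in `[0, 255]`, together with
#' the participant identifier and the post-application time point at which it
#' was taken (1, 5, 10, 15 or 20 minutes).
#'
#' @slot pixels numeric `H x W x 3` array, values in `[0, 255]`.
#' @slot participantId single string.
#' @slot timeMin integer, one of 1, 5, 10, 15, 20.
#' @slot sourcePath originating file path, or `NA` for in-memory images.
#' @export
setClass("NsrImage",
  slots = c(pixels = "array", participantId = "character",
            timeMin = "integer", sourcePath = "character"))

setValidity("NsrImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (!all(is.finite(object@pixels)))
    return("pixels must be finite")
  if (min(object@pixels) < 0 || max(object@pixels) > 255)
    return("pixel values must lie in [0, 255]")
  if (length(object@participantId) != 1L)
    return("participantId must have length 1")
  if (length(object@timeMin) != 1L || !(object@timeMin %in% NSR_TIMES))
    return("timeMin must be one of 1, 5, 10, 15, 20")
  TRUE
})

#' Construct an NsrImage
#'
#' @param pixels `H x W x 3` numeric array in `[0, 255]`.
#' @param participantId participant identifier.
#' @param timeMin minutes post-application (1, 5, 10, 15 or 20).
#' @param sourcePath optional originating path.
#' @return an [NsrImage-class] object.
#' @export
#' @examples
#' img <- NsrImage(array(128, c(4, 8, 3)), "p01", 5)
#' imageSize(img)
NsrImage <- function(pixels, participantId, timeMin,
                     sourcePath = NA_character_) {
  new("NsrImage", pixels = pixels,
      participantId = as.character(participantId),
      timeMin = as.integer(timeMin), sourcePath = as.character(sourcePath))
}

#' BinaryMask: a pixel-aligned boolean mask
#'
#' A strictly logical `H x W` matrix marking flushing pixels, the arm-label
#' fiducial, a white-reference patch, or an application-site region.
#'
#' @slot pixels logical matrix.
#' @slot kind one of `"flush"`, `"label"`, `"white_ref"`, `"site"`.
#' @export
setClass("BinaryMask", slots = c(pixels = "matrix", kind = "character"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("mask pixels must be logical")
  if (anyNA(object@pixels)) return("mask pixels must not contain NA")
  if (length(object@kind) != 1L || !(object@kind %in% MASK_KINDS))
    return(paste("kind must be one of:", paste(MASK_KINDS, collapse = ", ")))
  TRUE
})

#' Construct a BinaryMask
#'
#' @param pixels logical matrix (numeric input is interpreted as nonzero =
#'   foreground, tolerating annotation-tool exports).
#' @param kind mask kind; default `"flush"`.
#' @return a [BinaryMask-class] object.
#' @export
#' @examples
#' m <- BinaryMask(matrix(c(0, 1, 1, 0), 2), kind = "flush")
#' maskArea(m)
BinaryMask <- function(pixels, kind = "flush") {
  if (!is.logical(pixels)) {
    pixels <- matrix(pixels != 0, nrow(pixels), ncol(pixels))
  }
  new("BinaryMask", pixels = pixels, kind = kind)
}

#' NsrSegmenter: a U-Net flushing-area segmentation model
#'
#' Wraps the weights and configuration of the encoder-decoder segmentation
#' network (see [buildSegmenter()]). Weights live in a plain list so the
#' model can be serialized with `saveRDS()`.
#'
#' @slot weights named list of numeric arrays.
#' @slot config the [segModelConfig()] the model was built with.
#' @slot trained logical scalar.
#' @slot history per-epoch training log (`data.frame`).
#' @export
setClass("NsrSegmenter",
  slots = c(weights = "list", config = "list", trained = "logical",
            history = "data.frame"))

#' NsrFeatureSet: concentration-by-time NSR feature vectors
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay
#' (`"features"`, 20 rows) whose columns are participants. Rows are ordered
#' concentration-major (0.1, 0.01, 0.001, 0.0001 M) with time ascending
#' (1, 5, 10, 15, 20 min) within each concentration; `rowData` carries the
#' `(concentration, timeMin)` pair of each row. `colData$group` holds the
#' diagnostic group and `metadata(x)$scheme` records whether values are
#' objective 3-scale scores or direct normalized areas.
#'
#' @export
setClass("NsrFeatureSet",
         contains = "SummarizedExperiment")

setValidity("NsrFeatureSet", function(object) {
  if (nrow(object) != 20L) return("an NsrFeatureSet has exactly 20 feature rows")
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  md <- S4Vectors::metadata(object)
  if (is.null(md$scheme) || !(md$scheme %in% c("three_scale", "direct_area")))
    return("metadata(x)$scheme must be 'three_scale' or 'direct_area'")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) return("colData must contain 'group'")
  if (!all(as.character(cd$group) %in% NSR_GROUPS))
    return("groups must be HC, DP, BP or SZ")
  v <- SummarizedExperiment::assay(object, "features")
  if (md$scheme == "three_scale" && !all(v %in% 0:2))
    return("three_scale features must be scores in {0, 1, 2}")
  if (md$scheme == "direct_area" && any(v < 0))
    return("direct_area features must be nonnegative")
  TRUE
})

#' Construct an NsrFeatureSet
#'
#' @param values 20 x n numeric matrix (features x participants) in the
#'   documented row ordering, or an n x 20 matrix (auto-transposed).
#' @param participantId character vector of participant ids (column names).
#' @param group diagnostic group per participant (HC/DP/BP/SZ).
#' @param scheme `"three_scale"` or `"direct_area"`.
#' @return an [NsrFeatureSet-class].
#' @export
NsrFeatureSet <- function(values, participantId, group,
                          scheme = c("three_scale", "direct_area")) {
  scheme <- match.arg(scheme)
  values <- as.matrix(values)
  if (nrow(values) != 20L && ncol(values) == 20L) values <- t(values)
  if (nrow(values) != 20L) stop("feature matrix must have 20 feature rows")
  n <- ncol(values)
  if (length(participantId) != n || length(group) != n)
    stop("participantId and group must match the number of feature columns")
  ord <- featureOrdering()
  colnames(values) <- as.character(participantId)
  rownames(values) <- ord$name
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values),
    rowData = S4Vectors::DataFrame(concentration = ord$concentration,
                                   timeMin = ord$timeMin),
    colData = S4Vectors::DataFrame(
      participantId = as.character(participantId),
      group = factor(as.character(group), levels = NSR_GROUPS)),
    metadata = list(scheme = scheme))
  new("NsrFeatureSet", se)
}

# The documented 20-dim feature ordering: concentration-major, time ascending.
featureOrdering <- function() {
  labels <- c("0.1", "0.01", "0.001", "0.0001")
  conc <- rep(NSR_CONCENTRATIONS, each = length(NSR_TIMES))
  tm <- rep(NSR_TIMES, times = length(NSR_CONCENTRATIONS))
  data.frame(concentration = conc, timeMin = tm,
             name = sprintf("c%s_t%02d", rep(labels, each = 5), tm))
}

#' ScreeningResult: pooled cross-validated screening performance
#'
#' Result of [runScreening()]: the pooled out-of-fold 2x2 confusion matrix
#' (rows = actual HC / patient, columns = predicted), the derived metrics,
#' and the hyperparameters selected in each outer fold.
#'
#' @slot comparison e.g. `"HC vs DP"`.
#' @slot scheme feature scheme used.
#' @slot confusion 2x2 integer matrix, rows actual (HC, patient).
#' @slot metrics named list from [metricsFromConfusion()].
#' @slot bestParams list (one entry per outer fold) of selected parameters.
#' @slot nFolds number of outer folds.
#' @export
setClass("ScreeningResult",
  slots = c(comparison = "character", scheme = "character",
            confusion = "matrix", metrics = "list", bestParams = "list",
            nFolds = "integer"))

setValidity("ScreeningResult", function(object) {
  cm <- object@confusion
  if (!all(dim(cm) == c(2L, 2L))) return("confusion must be 2x2")
  if (any(cm < 0)) return("confusion entries must be nonnegative")
  m <- object@metrics
  need <- c("sensitivity", "specificity", "balancedAccuracy")
  if (!all(need %in% names(m))) return("metrics incomplete")
  if (abs(m$balancedAccuracy - (m$sensitivity + m$specificity) / 2) > 1e-12)
    return("balancedAccuracy must equal (sensitivity + specificity)/2")
  TRUE
})
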