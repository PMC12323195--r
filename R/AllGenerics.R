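#' @include AllClasses.R
NULL

#' Accessors for NSR objects
#'
#' Small accessor generics for the package's S4 containers: pixel payloads,
#' identifiers, mask areas and screening-result components.
#'
#' @param x an object.
#' @return the slot value (see individual methods).
#' @name nsr-accessors
NULL

#' @rdname nsr-accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))
#' @rdname nsr-accessors
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))
#' @rdname nsr-accessors
#' @export
setGeneric("timeMin", function(x) standardGeneric("timeMin"))
#' @rdname nsr-accessors
#' @export
setGeneric("imageSize", function(x) standardGeneric("imageSize"))
#' @rdname nsr-accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname nsr-accessors
#' @export
setGeneric("maskKind", function(x) standardGeneric("maskKind"))
#' @rdname nsr-accessors
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))
#' @rdname nsr-accessors
#' @export
setGeneric("featureScheme", function(x) standardGeneric("featureScheme"))
#' @rdname nsr-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname nsr-accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname nsr-accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname nsr-accessors
#' @export
setGeneric("screeningMetrics", function(x) standardGeneric("screeningMetrics"))
#' @rdname nsr-accessors
#' @export
setGeneric("balancedAccuracy", function(x) standardGeneric("balancedAccuracy"))

#' @rdname nsr-accessors
#' @export
setMethod("imagePixels", "NsrImage", function(x) x@pixels)
#' @rdname nsr-accessors
#' @export
setMethod("participantId", "NsrImage", function(x) x@participantId)
#' @rdname nsr-accessors
#' @export
setMethod("timeMin", "NsrImage", function(x) x@timeMin)
#' @rdname nsr-accessors
#' @export
setMethod("imageSize", "NsrImage", function(x) dim(x@pixels)[1:2])
#' @rdname nsr-accessors
#' @export
setMethod("imageSize", "BinaryMask", function(x) dim(x@pixels))
#' @rdname nsr-accessors
#' @export
setMethod("maskPixels", "BinaryMask", function(x) x@pixels)
#' @rdname nsr-accessors
#' @export
setMethod("maskKind", "BinaryMask", function(x) x@kind)
#' @rdname nsr-accessors
#' @export
setMethod("maskArea", "BinaryMask", function(x) sum(x@pixels))

#' @rdname nsr-accessors
#' @export
setMethod("featureScheme", "NsrFeatureSet",
          function(x) S4Vectors::metadata(x)$scheme)
#' @rdname nsr-accessors
#' @export
setMethod("featureMatrix", "NsrFeatureSet",
          function(x) t(SummarizedExperiment::assay(x, "features")))
#' @rdname nsr-accessors
#' @export
setMethod("groupLabels", "NsrFeatureSet",
          function(x) SummarizedExperiment::colData(x)$group)

#' @rdname nsr-accessors
#' @export
setMethod("confusionMatrix", "ScreeningResult", function(x) x@confusion)
#' @rdname nsr-accessors
#' @export
setMethod("screeningMetrics", "ScreeningResult", function(x) x@metrics)
#' @rdname nsr-accessors
#' @export
setMethod("balancedAccuracy", "ScreeningResult",
          function(x) x@metrics$balancedAccuracy)

setMethod("show", "NsrImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("NsrImage %d x %d, participant %s, %d min\n",
              d[1], d[2], object@participantId, object@timeMin))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryMask (%s) %d x %d, %d foreground px\n",
              object@kind, d[1], d[2], sum(object@pixels)))
})

setMethod("show", "NsrSegmenter", function(object) {
  np <- sum(vapply(object@weights, length, integer(1)))
  cat(sprintf(
    "NsrSegmenter: depth %d, base %d channels, %s parameters (%s)\n",
    object@config$encoderDepth, object@config$baseChannels,
    format(np, big.mark = ","),
    if (object@trained) "trained" else "untrained"))
  if (nrow(object@history) > 0)
    cat(sprintf("  best val Dice %.4f at epoch %d\n",
                max(object@history$valDice),
                which.max(object@history$valDice)))
})

setMethod("show", "ScreeningResult", function(object) {
  cat("ScreeningResult:", object@comparison,
      sprintf("(%s features, %d-fold CV)\n", object@scheme, object@nFolds))
  cm <- object@confusion
  cat("  pooled out-of-fold confusion (rows actual, cols predicted):\n")
  print(cm)
  m <- object@metrics
  cat(sprintf(
    "  balanced accuracy %.2f | sensitivity %.4f | specificity %.4f | overall %.2f\n",
    m$balancedAccuracy, m$sensitivity, m$specificity, m$overallAccuracy))
})
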