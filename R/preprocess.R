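#' @include AllClasses.R
NULL

#' Calibration parameters
#'
#' Parameters for device-independent normalization: the white reference used
#' for colour correction, the target pixel length of the arm-label fiducial
#' after scale calibration, and the model input shape. Only relative scale
#' is calibrated (images are normalised so the label measures
#' `targetLabelPx` along its major axis); the label's absolute physical size
#' is carried for provenance but not needed by the pipeline.
#'
#' @param whiteRefRegion optional [BinaryMask-class] or rectangle
#'   `c(row1, row2, col1, col2)` locating the label's white patch; when
#'   `NULL`, [whiteRefFromLabel()] locates it from the label mask.
#' @param labelRealSizeMm nominal physical label length (informative).
#' @param targetLabelPx label major-axis length after calibration, in px.
#' @param modelInputHw model input (height, width), default `c(128, 512)`.
#' @return a `CalibrationSpec` list.
#' @export
calibrationSpec <- function(whiteRefRegion = NULL, labelRealSizeMm = 50,
                            targetLabelPx = 120L,
                            modelInputHw = c(128L, 512L)) {
  if (labelRealSizeMm <= 0) stop("labelRealSizeMm must be positive")
  if (targetLabelPx <= 0) stop("targetLabelPx must be positive")
  if (any(modelInputHw <= 0)) stop("model input dimensions must be positive")
  structure(list(whiteRefRegion = whiteRefRegion,
                 labelRealSizeMm = labelRealSizeMm,
                 targetLabelPx = as.integer(targetLabelPx),
                 modelInputHw = as.integer(modelInputHw)),
            class = "CalibrationSpec")
}

regionIndices <- function(region, dims) {
  if (is(region, "BinaryMask")) {
    which(maskPixels(region))
  } else if (is.numeric(region) && length(region) == 4L) {
    rows <- region[1]:region[2]; cols <- region[3]:region[4]
    as.vector(outer(rows, (cols - 1) * dims[1], `+`))
  } else stop("white reference must be a BinaryMask or c(row1,row2,col1,col2)")
}

#' White balance against the label's white reference
#'
#' Perfect-reflector colour correction: each channel is scaled by
#' `255 / mean(channel over the white patch)` so the known-white reference
#' maps to pure white, cancelling the device/lighting colour cast. Output is
#' clipped to `[0, 255]`. The region mean (not max) is used as the white
#' estimate, which is robust to specular noise.
#'
#' @param image an [NsrImage-class].
#' @param whiteRef [BinaryMask-class] or rectangle `c(row1, row2, col1,
#'   col2)` in image coordinates.
#' @return the corrected [NsrImage-class].
#' @export
whiteBalance <- function(image, whiteRef) {
  px <- imagePixels(image)
  idx <- regionIndices(whiteRef, dim(px))
  if (length(idx) == 0) stop("white reference region is empty")
  npx <- prod(dim(px)[1:2])
  gains <- vapply(1:3, function(ch) {
    m <- mean(px[idx + (ch - 1) * npx])
    if (m <= 0) stop("white reference channel mean is zero")
    255 / m
  }, numeric(1))
  out <- px
  for (ch in 1:3) out[, , ch] <- clip255(px[, , ch] * gains[ch])
  initialize(image, pixels = out)
}

#' Locate the white reference patch inside the label
#'
#' The arm label contains a white section whose exact position is not known
#' a priori; this takes the brightest connected subregion of the label mask
#' (pixels within 8% of the label's peak luminance, largest connected
#' component) as the white reference.
#'
#' @param image an [NsrImage-class].
#' @param labelMask the label [BinaryMask-class].
#' @return a [BinaryMask-class] of kind `"white_ref"`.
#' @export
whiteRefFromLabel <- function(image, labelMask) {
  px <- imagePixels(image)
  lm <- maskPixels(labelMask)
  if (!all(dim(px)[1:2] == dim(lm))) stop("label mask shape differs")
  if (!any(lm)) stop("label mask is empty")
  lum <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  lum[!lm] <- -Inf
  bright <- lum >= 0.92 * max(lum)
  cc <- EBImage::bwlabel(t(bright))
  sizes <- tabulate(cc[cc > 0])
  best <- which.max(sizes)
  BinaryMask(t(cc == best), kind = "white_ref")
}

resizeImageArr <- function(px, h, w) {
  fromEB(EBImage::resize(toEB(px), w = w, h = h, filter = "bilinear"))
}

resizeMaskMat <- function(m, h, w) {
  r <- EBImage::resize(EBImage::Image(t(m) * 1.0), w = w, h = h,
                       filter = "none")
  t(EBImage::imageData(r)) > 0.5
}

labelMajorAxisPx <- function(labelMask) {
  lm <- maskPixels(labelMask)
  rows <- range(which(rowSums(lm) > 0))
  cols <- range(which(colSums(lm) > 0))
  max(diff(rows), diff(cols)) + 1L
}

#' Scale calibration from the arm-label fiducial
#'
#' Rescales the image (and any accompanying masks) by
#' `s = targetLabelPx / measuredLabelPx`, where the measured label size is
#' the major-axis length of the label mask's bounding box. After
#' calibration the label measures `targetLabelPx` (+/- 1 px from
#' rasterisation) in every image, cancelling camera-distance variation.
#'
#' @param image an [NsrImage-class].
#' @param labelMask the label [BinaryMask-class].
#' @param spec a [calibrationSpec()].
#' @param masks optional named list of further [BinaryMask-class] objects to
#'   transform identically (e.g. the flushing ground truth).
#' @return list with `image`, `labelMask`, `masks` and the `scale` applied.
#' @export
calibrateScale <- function(image, labelMask, spec = calibrationSpec(),
                           masks = list()) {
  if (maskArea(labelMask) < 9) stop("degenerate label mask (area < 9 px)")
  measured <- labelMajorAxisPx(labelMask)
  s <- spec$targetLabelPx / measured
  px <- imagePixels(image)
  h <- max(1L, round(dim(px)[1] * s)); w <- max(1L, round(dim(px)[2] * s))
  if (abs(s - 1) < 1e-9) {
    return(list(image = image, labelMask = labelMask, masks = masks,
                scale = 1))
  }
  out <- initialize(image, pixels = resizeImageArr(px, h, w))
  lm <- BinaryMask(resizeMaskMat(maskPixels(labelMask), h, w), "label")
  ms <- lapply(masks, function(m)
    BinaryMask(resizeMaskMat(maskPixels(m), h, w), maskKind(m)))
  list(image = out, labelMask = lm, masks = ms, scale = s)
}

#' Resize to the model input shape
#'
#' Bilinear interpolation for the image; nearest-neighbour for masks, which
#' therefore stay strictly boolean.
#'
#' @param image an [NsrImage-class].
#' @param mask optional [BinaryMask-class] (or named list of them).
#' @param spec a [calibrationSpec()] carrying `modelInputHw`.
#' @return list with `image` and (when given) `mask`.
#' @export
resizeToInput <- function(image, mask = NULL, spec = calibrationSpec()) {
  hw <- spec$modelInputHw
  px <- imagePixels(image)
  img <- if (all(dim(px)[1:2] == hw)) image
         else initialize(image, pixels = resizeImageArr(px, hw[1], hw[2]))
  res <- list(image = img)
  doMask <- function(m) {
    if (all(dim(maskPixels(m)) == hw)) m
    else BinaryMask(resizeMaskMat(maskPixels(m), hw[1], hw[2]), maskKind(m))
  }
  if (!is.null(mask)) {
    res$mask <- if (is(mask, "BinaryMask")) doMask(mask)
                else lapply(mask, doMask)
  }
  res
}

#' Full preprocessing of one photograph
#'
#' Convenience chain used by the pipeline: white balance against the label's
#' white patch (located via [whiteRefFromLabel()] unless a region is given),
#' scale calibration from the label fiducial, and resize to the model input
#' shape, with any supplied masks transformed alongside the image.
#'
#' @param image an [NsrImage-class].
#' @param labelMask the label [BinaryMask-class].
#' @param flushMask optional flushing ground-truth mask.
#' @param whiteRef optional explicit white-reference region.
#' @param spec a [calibrationSpec()].
#' @return list with `image`, `labelMask`, `flushMask` (or `NULL`) at the
#'   model input shape, plus the calibration `scale`.
#' @export
preprocessImage <- function(image, labelMask, flushMask = NULL,
                            whiteRef = NULL, spec = calibrationSpec()) {
  if (is.null(whiteRef)) whiteRef <- spec$whiteRefRegion
  if (is.null(whiteRef)) whiteRef <- whiteRefFromLabel(image, labelMask)
  wb <- whiteBalance(image, whiteRef)
  masks <- list(label = labelMask)
  if (!is.null(flushMask)) masks$flush <- flushMask
  cal <- calibrateScale(wb, labelMask, spec, masks = masks["flush" ==
                                                             names(masks)])
  allMasks <- c(list(label = cal$labelMask), cal$masks)
  rs <- resizeToInput(cal$image, allMasks, spec)
  list(image = rs$image, labelMask = rs$mask$label,
       flushMask = rs$mask$flush, scale = cal$scale)
}

#' Runtime augmentation parameters
#'
#' Magnitudes for the paired geometric transforms (rotation, shift, scale,
#' flips) and image-only photometric jitter (brightness, contrast,
#' saturation) drawn per training sample. Defaults are mild: +/-15 degrees,
#' +/-5% shift, scale 0.9-1.1, 50% flips, +/-20% photometric jitter.
#'
#' @param maxRotationDeg,maxShiftFrac,scaleRange geometric magnitudes.
#' @param pHflip,pVflip flip probabilities.
#' @param brightnessDelta,contrastDelta,saturationDelta photometric
#'   half-ranges (multiplicative, around 1).
#' @param seed optional default seed.
#' @return an `AugmentParams` list.
#' @export
augmentParams <- function(maxRotationDeg = 15, maxShiftFrac = 0.05,
                          scaleRange = c(0.9, 1.1), pHflip = 0.5,
                          pVflip = 0.5, brightnessDelta = 0.2,
                          contrastDelta = 0.2, saturationDelta = 0.2,
                          seed = NULL) {
  stopifnot(maxRotationDeg >= 0, maxShiftFrac >= 0,
            all(scaleRange > 0), pHflip >= 0, pHflip <= 1,
            pVflip >= 0, pVflip <= 1, brightnessDelta >= 0,
            contrastDelta >= 0, saturationDelta >= 0)
  structure(list(maxRotationDeg = maxRotationDeg,
                 maxShiftFrac = maxShiftFrac, scaleRange = scaleRange,
                 pHflip = pHflip, pVflip = pVflip,
                 brightnessDelta = brightnessDelta,
                 contrastDelta = contrastDelta,
                 saturationDelta = saturationDelta, seed = seed),
            class = "AugmentParams")
}

affineWarp <- function(px, m, bilinear = TRUE) {
  out <- EBImage::affine(toEB(px), m,
                         filter = if (bilinear) "bilinear" else "none",
                         bg.col = 0)
  fromEB(out)
}

#' Paired random augmentation of an image and its mask
#'
#' Draws one random geometric transform (rotation about the centre, shift,
#' isotropic scale, flips) and applies it identically to image and mask
#' (bilinear vs. nearest interpolation), then applies photometric jitter to
#' the image only. Output shapes equal input shapes; the mask stays
#' boolean. With a fixed `drawSeed` the output is bit-reproducible.
#'
#' @param image an [NsrImage-class].
#' @param mask the paired [BinaryMask-class].
#' @param params an [augmentParams()].
#' @param drawSeed seed for this draw (falls back to `params$seed`).
#' @return list with `image` and `mask`.
#' @export
augmentPair <- function(image, mask, params = augmentParams(),
                        drawSeed = NULL) {
  px <- imagePixels(image)
  mk <- maskPixels(mask)
  if (!all(dim(px)[1:2] == dim(mk))) stop("image and mask are not aligned")
  seed <- if (is.null(drawSeed)) params$seed else drawSeed
  withSeed(seed, {
    ang <- if (params$maxRotationDeg > 0)
      runif(1, -params$maxRotationDeg, params$maxRotationDeg) else 0
    shift <- if (params$maxShiftFrac > 0)
      runif(2, -params$maxShiftFrac, params$maxShiftFrac) *
        rev(dim(mk)) else c(0, 0)  # (x, y) order
    sc <- if (diff(range(params$scaleRange)) > 0 ||
              any(params$scaleRange != 1))
      runif(1, params$scaleRange[1], params$scaleRange[2]) else 1
    hflip <- runif(1) < params$pHflip
    vflip <- runif(1) < params$pVflip
    jitter <- function(delta) if (delta > 0) runif(1, 1 - delta, 1 + delta)
                              else 1
    fb <- jitter(params$brightnessDelta)
    fc <- jitter(params$contrastDelta)
    fs <- jitter(params$saturationDelta)

    if (ang != 0 || any(shift != 0) || sc != 1) {
      th <- ang * pi / 180
      M <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      ctr <- rev(dim(mk)) / 2  # EBImage (x, y)
      tv <- ctr + shift - M %*% ctr
      m <- rbind(t(M), as.vector(tv))
      px <- affineWarp(px, m, bilinear = TRUE)
      mk3 <- affineWarp(array(rep(mk * 1, 3), c(dim(mk), 3)), m,
                        bilinear = FALSE)
      mk <- mk3[, , 1] > 0.5
    }
    if (hflip) { px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
                 mk <- mk[, rev(seq_len(ncol(mk))), drop = FALSE] }
    if (vflip) { px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
                 mk <- mk[rev(seq_len(nrow(mk))), , drop = FALSE] }
    if (fb != 1) px <- clip255(px * fb)
    if (fc != 1) px <- clip255((px - 127.5) * fc + 127.5)
    if (fs != 1) {
      gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
      for (ch in 1:3) px[, , ch] <- clip255(gray + fs * (px[, , ch] - gray))
    }
    list(image = initialize(image, pixels = px),
         mask = BinaryMask(mk, maskKind(mask)))
  })
}
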