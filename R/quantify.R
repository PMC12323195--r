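#' @include AllClasses.R
NULL

#' Application-site geometry
#'
#' The four niacin application sites lie side by side along the long (512
#' px) axis of the calibrated image, ordered by descending concentration
#' (0.1, 0.01, 0.001, 0.0001 M). By default the application zone (the image
#' minus the label area on the left) is split into four equal-width column
#' bands; custom region masks may be supplied instead when the patch
#' orientation differs.
#'
#' @param zoneStart,zoneEnd first and last column of the application zone.
#' @param inputHw image shape the geometry refers to.
#' @param concentrations site concentrations in band order.
#' @param regions optional list of 4 [BinaryMask-class] site regions,
#'   overriding the band partition.
#' @return a `SiteGeometry` list.
#' @export
siteGeometry <- function(zoneStart = 129L, zoneEnd = 512L,
                         inputHw = c(128L, 512L),
                         concentrations = c(0.1, 0.01, 0.001, 0.0001),
                         regions = NULL) {
  if (length(concentrations) != 4L) stop("exactly 4 concentrations expected")
  if (is.null(regions)) {
    edges <- round(seq(zoneStart - 1L, zoneEnd, length.out = 5L))
    regions <- lapply(1:4, function(i) {
      m <- matrix(FALSE, inputHw[1], inputHw[2])
      m[, (edges[i] + 1L):edges[i + 1L]] <- TRUE
      BinaryMask(m, kind = "site")
    })
  } else {
    if (length(regions) != 4L) stop("exactly 4 site regions expected")
  }
  ov <- Reduce(`+`, lapply(regions, maskPixels))
  if (any(ov > 1)) stop("site regions overlap")
  structure(list(concentrations = concentrations, regions = regions,
                 inputHw = as.integer(inputHw)),
            class = "SiteGeometry")
}

#' Partition a flushing mask into the four application sites
#'
#' Each flushing pixel is attributed to the site region containing it;
#' pixels outside every region are dropped and counted. Site areas plus the
#' dropped count always sum to the total flushing area.
#'
#' @param flushMask a flushing [BinaryMask-class] at the geometry's shape.
#' @param geometry a [siteGeometry()].
#' @return list with `siteMasks` (4 [BinaryMask-class]), `areas` (pixel
#'   counts named by concentration) and `dropped` (out-of-zone pixels).
#' @export
assignSites <- function(flushMask, geometry = siteGeometry()) {
  fm <- maskPixels(flushMask)
  if (!all(dim(fm) == geometry$inputHw))
    stop("flush mask shape does not match the geometry")
  siteMasks <- lapply(geometry$regions, function(r)
    BinaryMask(fm & maskPixels(r), kind = "flush"))
  areas <- vapply(siteMasks, maskArea, numeric(1))
  names(areas) <- as.character(geometry$concentrations)
  list(siteMasks = siteMasks, areas = areas,
       dropped = sum(fm) - sum(areas))
}

#' Normalized flushing area
#'
#' `A_norm = A_detected / A_label`: the detected flushing area divided by
#' the area of the arm-label fiducial, making the measurement independent of
#' image resolution and camera distance.
#'
#' @param aDetected detected flushing pixel count(s).
#' @param aLabel label pixel count (> 0).
#' @return `aDetected / aLabel`.
#' @export
#' @examples
#' computeANorm(327, 2000)
computeANorm <- function(aDetected, aLabel) {
  if (any(aLabel <= 0)) stop("label area must be positive")
  aDetected / aLabel
}

#' Objective 3-scale score cut-points
#'
#' Defaults are the published constants 0.1091 and 0.1598 (kept verbatim for
#' bit-compatibility with reported results rather than re-derived; see
#' [deriveThresholds()]).
#'
#' @param t0,t1 lower and upper A_norm cut-points, `0 < t0 < t1`.
#' @return a `ScoreScale` list.
#' @export
scoreScale <- function(t0 = 0.1091, t1 = 0.1598) {
  if (!(t0 > 0 && t1 > t0)) stop("need 0 < t0 < t1")
  structure(list(t0 = t0, t1 = t1), class = "ScoreScale")
}

#' Derive 3-scale cut-points from per-score A_norm means
#'
#' The objective scale collapses manual scores 2 and 3 (whose A_norm means
#' differ by only 0.0004) and places each cut-point midway between adjacent
#' score means: `t0 = (mean0 + mean1)/2`, `t1 = (mean1 + mean2)/2`. Applied
#' to the reference distribution statistics ([referenceScoreStats()]) this
#' reproduces the published upper cut-point 0.1598 exactly; the lower
#' midpoint is 0.10915, which the published tables truncate to 0.1091.
#'
#' @param stats data.frame with a `mean` column for manual scores 0, 1, 2
#'   (rows in score order; extra rows ignored).
#' @return named numeric `c(t0, t1)`.
#' @export
#' @examples
#' deriveThresholds(referenceScoreStats())
deriveThresholds <- function(stats = referenceScoreStats()) {
  m <- stats$mean
  if (length(m) < 3) stop("means for scores 0, 1, 2 are required")
  if (!(m[1] < m[2] && m[2] < m[3]))
    stop("per-score means must be strictly increasing")
  c(t0 = (m[1] + m[2]) / 2, t1 = (m[2] + m[3]) / 2)
}

#' Apply the objective 3-scale score
#'
#' Score 0 for `A_norm < t0`, score 1 for `t0 <= A_norm < t1`, score 2
#' otherwise (lower bounds inclusive).
#'
#' @param aNorm normalized area(s), `>= 0`.
#' @param scale a [scoreScale()].
#' @return integer score(s) in `{0, 1, 2}`.
#' @export
#' @examples
#' score3Scale(c(0.05, 0.1091, 0.1598))
score3Scale <- function(aNorm, scale = scoreScale()) {
  if (any(aNorm < 0)) stop("aNorm must be nonnegative")
  ifelse(aNorm < scale$t0, 0L, ifelse(aNorm < scale$t1, 1L, 2L))
}

#' Assemble the 20-dimensional feature vector
#'
#' Flattens a complete 4 (concentration, descending) x 5 (time, ascending)
#' grid of normalized areas into the documented feature ordering
#' (concentration-major, time ascending), either as objective 3-scale scores
#' or as the direct A_norm values.
#'
#' @param grid 4x5 numeric matrix of A_norm values; rows = concentrations
#'   0.1, 0.01, 0.001, 0.0001 M, columns = 1, 5, 10, 15, 20 min.
#' @param scheme `"three_scale"` or `"direct_area"`.
#' @param scale the [scoreScale()] used for `"three_scale"`.
#' @return named numeric vector of length 20.
#' @export
buildFeatureVector <- function(grid, scheme = c("three_scale", "direct_area"),
                               scale = scoreScale()) {
  scheme <- match.arg(scheme)
  grid <- as.matrix(grid)
  if (!all(dim(grid) == c(4L, 5L)))
    stop("grid must be 4 concentrations x 5 time points")
  if (anyNA(grid)) {
    bad <- which(is.na(grid), arr.ind = TRUE)[1, ]
    stop(sprintf("missing measurement at (%s M, %d min)",
                 format(NSR_CONCENTRATIONS[bad[1]], scientific = FALSE),
                 NSR_TIMES[bad[2]]))
  }
  v <- as.vector(t(grid))  # concentration-major, time ascending
  if (scheme == "three_scale") v <- score3Scale(v, scale)
  names(v) <- featureOrdering()$name
  v
}

#' Quantify one image: per-site measurements from predicted masks
#'
#' Splits the flushing mask into the four sites and normalizes each site
#' area by the label area measured on the same calibrated/resized grid (so
#' the ratio is resolution-invariant).
#'
#' @param flushMask flushing [BinaryMask-class] (typically from
#'   [predictMask()]).
#' @param labelMask label [BinaryMask-class] on the same pixel grid.
#' @param geometry a [siteGeometry()].
#' @param timeMin optional time annotation copied into the result.
#' @return data.frame with one row per site: `concentration`, `timeMin`,
#'   `aDetected`, `aLabel`, `aNorm`.
#' @export
quantifyImage <- function(flushMask, labelMask, geometry = siteGeometry(),
                          timeMin = NA_integer_) {
  aLabel <- maskArea(labelMask)
  sites <- assignSites(flushMask, geometry)
  data.frame(concentration = geometry$concentrations,
             timeMin = as.integer(timeMin),
             aDetected = as.numeric(sites$areas), aLabel = aLabel,
             aNorm = computeANorm(as.numeric(sites$areas), aLabel))
}
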