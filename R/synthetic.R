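#' @include AllClasses.R
NULL

#' Synthetic cohort configuration
#'
#' Defaults mirror the open dataset's composition: 60 healthy controls and
#' 20 participants in each of the depression, bipolar and schizophrenia
#' groups (120 participants), photographed at 1, 5, 10, 15 and 20 minutes
#' (600 image slots), with four application-site concentrations.
#'
#' @param nHc healthy controls.
#' @param nPerDisorder participants per disorder group.
#' @param timePoints assessment times (minutes).
#' @param concentrations site concentrations (M), descending.
#' @param seed cohort RNG seed.
#' @return a `CohortConfig` list.
#' @export
cohortConfig <- function(nHc = 60, nPerDisorder = 20,
                         timePoints = c(1, 5, 10, 15, 20),
                         concentrations = c(0.1, 0.01, 0.001, 0.0001),
                         seed = 1) {
  stopifnot(nHc > 0, nPerDisorder > 0)
  structure(list(nHc = as.integer(nHc),
                 nPerDisorder = as.integer(nPerDisorder),
                 timePoints = as.integer(timePoints),
                 concentrations = concentrations, seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Flushing kinetics of the synthetic cohort
#'
#' The expected normalized area follows saturating growth,
#' `a(t) = plateau * subj * (1 - exp(-rate * max(t - delay, 0))) * amp(conc)`,
#' plus Gaussian measurement noise, clipped at 0. Patients flush more
#' slowly (lower rate, longer onset delay) and plateau lower than healthy
#' controls; the amplitude multiplier decreases with dilution and is near
#' zero at 0.0001 M, where flushing is rarely induced. `subj` is a
#' per-participant log-normal susceptibility factor creating the
#' between-subject overlap that keeps groups statistically, not
#' deterministically, separable. `effectSize` scales the patient-vs-HC
#' parameter differences (0 = identical kinetics for all groups, 1 =
#' default effect).
#'
#' @param hcRate,patientRate median growth rates (per minute).
#' @param hcPlateau,patientPlateau median plateau A_norm at 0.1 M.
#' @param hcDelay,patientDelay median onset delays (minutes).
#' @param amplitude per-concentration multipliers (descending
#'   concentration).
#' @param noiseSd per-measurement Gaussian noise (A_norm units).
#' @param participantSd sd of the log-normal susceptibility factor
#'   multiplying the plateau.
#' @param rateSd sd of the per-participant log-normal rate factor.
#' @param delaySd sd of the per-participant delay jitter (minutes).
#' @param effectSize scaling of the group effect in `[0, 1]`.
#' @return a `FlushKinetics` list.
#' @export
flushKinetics <- function(hcRate = 0.30, patientRate = 0.16,
                          hcPlateau = 0.21, patientPlateau = 0.18,
                          hcDelay = 1, patientDelay = 2.5,
                          amplitude = c(1, 0.8, 0.45, 0.04),
                          noiseSd = 0.03, participantSd = 0.35,
                          rateSd = 0.35, delaySd = 1,
                          effectSize = 1) {
  if (any(diff(amplitude) > 0))
    stop("amplitude must be non-increasing with dilution")
  if (patientRate > hcRate)
    stop("patients must not flush faster than healthy controls")
  blend <- function(hc, pat) hc + effectSize * (pat - hc)
  structure(list(rate = c(HC = hcRate, blend(hcRate, patientRate)),
                 plateau = c(HC = hcPlateau, blend(hcPlateau,
                                                   patientPlateau)),
                 delay = c(HC = hcDelay, blend(hcDelay, patientDelay)),
                 amplitude = amplitude, noiseSd = noiseSd,
                 participantSd = participantSd, rateSd = rateSd,
                 delaySd = delaySd, effectSize = effectSize),
            class = "FlushKinetics")
}

kineticsFor <- function(kinetics, group) {
  i <- if (group == "HC") 1L else 2L
  list(rate = kinetics$rate[i], plateau = kinetics$plateau[i],
       delay = kinetics$delay[i])
}

#' Generate a synthetic cohort with true normalized areas
#'
#' Draws participants per the cohort config and, for each, a 4x5 grid of
#' true A_norm values (concentration descending x time ascending) from the
#' kinetics model. Deterministic given the config seed.
#'
#' @param config a [cohortConfig()].
#' @param kinetics a [flushKinetics()].
#' @return list with `participants` (`data.frame(id, group)`) and `aNorm`
#'   (4 x 5 x n array, participant slices named by id).
#' @export
generateCohort <- function(config = cohortConfig(),
                           kinetics = flushKinetics()) {
  groups <- c(rep("HC", config$nHc),
              rep(c("DP", "BP", "SZ"), each = config$nPerDisorder))
  ids <- sprintf("%s%03d", groups,
                 unlist(lapply(c(config$nHc, rep(config$nPerDisorder, 3)),
                               seq_len)))
  n <- length(ids)
  nc <- length(config$concentrations); nt <- length(config$timePoints)
  aNorm <- array(0, c(nc, nt, n),
                 dimnames = list(NULL, NULL, ids))
  withSeed(config$seed, {
    for (p in seq_len(n)) {
      kp <- kineticsFor(kinetics, groups[p])
      subjAmp <- exp(rnorm(1, 0, kinetics$participantSd))
      subjRate <- kp$rate * exp(rnorm(1, 0, kinetics$rateSd))
      subjDelay <- max(0, kp$delay + rnorm(1, 0, kinetics$delaySd))
      mu <- outer(kinetics$amplitude[seq_len(nc)],
                  1 - exp(-subjRate * pmax(config$timePoints - subjDelay,
                                           0))) *
        kp$plateau * subjAmp
      eps <- if (kinetics$noiseSd > 0)
        matrix(rnorm(nc * nt, 0, kinetics$noiseSd), nc, nt)
      else 0
      aNorm[, , p] <- pmax(mu + eps, 0)
    }
  })
  list(participants = data.frame(id = ids, group = groups,
                                 stringsAsFactors = FALSE),
       aNorm = aNorm)
}

#' Synthetic image rendering configuration
#'
#' Geometry and photometry of the rendered forearm photographs, at camera
#' distance 1: a 160 x 640 canvas, a label rectangle with a white patch on
#' the left, and four application sites in equal bands along the remaining
#' axis (matching the default [siteGeometry()] after the 0.8x resize to the
#' 128 x 512 model shape). A per-image camera-distance factor scales the
#' whole canvas; a per-device diagonal RGB gain in `castRange` simulates
#' uncorrected white balance; blur and pixel noise complete the camera
#' model.
#'
#' @param canvasHw canvas (height, width) at distance 1.
#' @param labelRect label rows/cols `c(r1, r2, c1, c2)` at distance 1.
#' @param whiteRect white-patch rows/cols inside the label.
#' @param siteCentersX site centre columns; `siteCenterY` the common row.
#' @param skinColor,labelColor,whiteColor,flushColor RGB triples (0-255).
#' @param castRange per-channel gain range of the device colour cast.
#' @param blurSd Gaussian blur sigma (px).
#' @param noiseSd additive pixel noise sd (intensity levels).
#' @param distanceRange camera-distance factor range.
#' @return a `RenderConfig` list.
#' @export
renderConfig <- function(canvasHw = c(160L, 640L),
                         labelRect = c(41L, 120L, 25L, 144L),
                         whiteRect = c(49L, 112L, 101L, 140L),
                         siteCentersX = c(221, 341, 461, 581),
                         siteCenterY = 80,
                         skinColor = c(205, 162, 144),
                         labelColor = c(182, 186, 198),
                         whiteColor = c(250, 250, 250),
                         flushColor = c(226, 92, 92),
                         castRange = c(0.7, 1.3), blurSd = 0.8,
                         noiseSd = 2.5, distanceRange = c(0.85, 1.2)) {
  stopifnot(whiteRect[1] >= labelRect[1], whiteRect[2] <= labelRect[2],
            whiteRect[3] >= labelRect[3], whiteRect[4] <= labelRect[4])
  structure(list(canvasHw = as.integer(canvasHw), labelRect = labelRect,
                 whiteRect = whiteRect, siteCentersX = siteCentersX,
                 siteCenterY = siteCenterY, skinColor = skinColor,
                 labelColor = labelColor, whiteColor = whiteColor,
                 flushColor = flushColor, castRange = castRange,
                 blurSd = blurSd, noiseSd = noiseSd,
                 distanceRange = distanceRange),
            class = "RenderConfig")
}

#' Render one synthetic arm photograph with ground-truth masks
#'
#' Draws the skin background, the label with its white patch and ID marks,
#' and one flushing disc per application site whose pixel area equals the
#' true `aNorm` times the label pixel area (rasterisation-exact to within a
#' few percent). The ground-truth masks are defined before blur, colour
#' cast and noise are applied, mirroring human annotation of the visible
#' erythema. A site whose disc would overflow its band is clipped with a
#' warning.
#'
#' @param aNorm numeric vector of 4 true normalized areas (descending
#'   concentration).
#' @param participantId,timeMin image annotations.
#' @param config a [renderConfig()].
#' @param distance camera-distance factor (drawn from `distanceRange` when
#'   `NULL`).
#' @param cast length-3 RGB gain (drawn from `castRange` when `NULL`).
#' @param seed per-image RNG seed (bit-reproducible renders).
#' @return list with `image` ([NsrImage-class]), `flushMask`, `labelMask`,
#'   `whiteRefMask` ([BinaryMask-class]).
#' @export
renderImage <- function(aNorm, participantId = "synth", timeMin = 5L,
                        config = renderConfig(), distance = NULL,
                        cast = NULL, seed = NULL) {
  stopifnot(length(aNorm) == 4L, all(aNorm >= 0))
  withSeed(seed, {
    if (is.null(distance))
      distance <- runif(1, config$distanceRange[1], config$distanceRange[2])
    if (is.null(cast))
      cast <- runif(3, config$castRange[1], config$castRange[2])
    # chromatic cast only: cameras auto-expose, so the brightest channel is
    # kept at unit gain and the white patch never saturates at render time
    cast <- cast / max(cast)
    h <- round(config$canvasHw[1] * distance)
    w <- round(config$canvasHw[2] * distance)
    sc <- function(v) pmax(1, round(v * distance))

    px <- array(0, c(h, w, 3))
    # skin with a mild vertical shading gradient
    shade <- 1 - 0.08 * abs(seq(-1, 1, length.out = h))
    for (ch in 1:3)
      px[, , ch] <- outer(shade * config$skinColor[ch], rep(1, w))

    lr <- sc(config$labelRect); wr <- sc(config$whiteRect)
    labelMask <- matrix(FALSE, h, w)
    labelMask[lr[1]:lr[2], lr[3]:lr[4]] <- TRUE
    whiteMask <- matrix(FALSE, h, w)
    whiteMask[wr[1]:wr[2], wr[3]:wr[4]] <- TRUE
    for (ch in 1:3) {
      pl <- px[, , ch]
      pl[labelMask] <- config$labelColor[ch]
      pl[whiteMask] <- config$whiteColor[ch]
      px[, , ch] <- pl
    }
    # deterministic dark ID marks on the label's left part
    markRows <- lr[1] + round((lr[2] - lr[1]) * c(0.2, 0.45, 0.7))
    for (mr in markRows) {
      rr <- mr:min(mr + max(1, round(2 * distance)), lr[2])
      cc <- lr[3] + round((wr[3] - lr[3]) * 0.15):round((wr[3] - lr[3]) * 0.7)
      for (ch in 1:3) px[rr, cc, ch] <- 60
    }

    labelArea <- sum(labelMask)
    flushMask <- matrix(FALSE, h, w)
    cy <- config$siteCenterY * distance
    bandHalf <- diff(config$siteCentersX[1:2]) / 2 * distance
    rowIdx <- matrix(seq_len(h), h, w)
    colIdx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (s in 1:4) {
      if (aNorm[s] <= 0) next
      targetArea <- aNorm[s] * labelArea
      r <- sqrt(targetArea / pi)
      rMax <- min(bandHalf - 2, cy - 2, h - cy - 2)
      if (r > rMax) {
        warning(sprintf("site %d flushing area exceeds its region; clipped",
                        s))
        r <- rMax
      }
      cx <- config$siteCentersX[s] * distance
      d2 <- (rowIdx - cy)^2 + (colIdx - cx)^2
      disc <- d2 <= r^2
      flushMask <- flushMask | disc
      # soft-edged erythema: full colour inside, fading over ~2 px
      alpha <- pmin(pmax((r + 2 - sqrt(d2)) / 2, 0), 1) * 0.9
      keep <- alpha > 0
      for (ch in 1:3)
        px[, , ch][keep] <- (1 - alpha[keep]) * px[, , ch][keep] +
          alpha[keep] * config$flushColor[ch]
    }

    if (config$blurSd > 0)
      px <- fromEB(EBImage::gblur(toEB(px),
                                  sigma = config$blurSd * distance))
    for (ch in 1:3) px[, , ch] <- px[, , ch] * cast[ch]
    if (config$noiseSd > 0)
      px <- px + array(rnorm(length(px), 0, config$noiseSd), dim(px))
    px <- round(clip255(px))

    list(image = NsrImage(px, participantId, timeMin),
         flushMask = BinaryMask(flushMask, "flush"),
         labelMask = BinaryMask(labelMask, "label"),
         whiteRefMask = BinaryMask(whiteMask, "white_ref"))
  })
}

# Manual-score emulation used for the synthetic info table: the objective
# cut-points plus a notional "beyond the patch" level at 0.21.
manualScoreFromANorm <- function(aNorm) {
  ifelse(aNorm < 0.1091, 0L,
         ifelse(aNorm < 0.1598, 1L, ifelse(aNorm < 0.21, 2L, 3L)))
}

#' Generate a full synthetic dataset in memory
#'
#' Cohort generation plus rendering of every (participant, time) slot, with
#' a per-participant device colour cast, per-image camera distance, and the
#' info table of emulated manual scores. The result matches the layout
#' written by [writeNsrDataset()] / read by [readNsrDataset()].
#'
#' @param config a [cohortConfig()] (default: the full 120-participant,
#'   600-image cohort).
#' @param kinetics a [flushKinetics()].
#' @param render a [renderConfig()].
#' @param participants optional subset of participant ids to render.
#' @return list with `images`, `flushMasks`, `labelMasks`, `whiteRefMasks`
#'   (named lists keyed `<id>_t<mm>`), `info` (`data.frame`), `cohort`.
#' @export
generateSyntheticDataset <- function(config = cohortConfig(),
                                     kinetics = flushKinetics(),
                                     render = renderConfig(),
                                     participants = NULL) {
  cohort <- generateCohort(config, kinetics)
  ids <- cohort$participants$id
  if (!is.null(participants)) ids <- intersect(ids, participants)
  images <- list(); flushMasks <- list(); labelMasks <- list()
  whiteRefMasks <- list(); info <- NULL
  for (p in seq_along(ids)) {
    id <- ids[p]
    pi <- match(id, cohort$participants$id)
    castSeed <- subSeed(config$seed, 7000 + pi)
    cast <- withSeed(castSeed,
                     runif(3, render$castRange[1], render$castRange[2]))
    for (ti in seq_along(config$timePoints)) {
      tm <- config$timePoints[ti]
      key <- sprintf("%s_t%02d", id, tm)
      rend <- renderImage(cohort$aNorm[, ti, pi], id, tm, render,
                          cast = cast,
                          seed = subSeed(config$seed, 97L * pi + ti))
      images[[key]] <- rend$image
      flushMasks[[key]] <- rend$flushMask
      labelMasks[[key]] <- rend$labelMask
      whiteRefMasks[[key]] <- rend$whiteRefMask
      sc <- manualScoreFromANorm(cohort$aNorm[, ti, pi])
      info <- rbind(info, data.frame(
        participant_id = id, group = cohort$participants$group[pi],
        time_min = tm, "score_0.1M" = sc[1], "score_0.01M" = sc[2],
        "score_0.001M" = sc[3], "score_0.0001M" = sc[4],
        check.names = FALSE))
    }
  }
  list(images = images, flushMasks = flushMasks, labelMasks = labelMasks,
       whiteRefMasks = whiteRefMasks, info = info, cohort = cohort)
}

#' Feature table straight from the true A_norm grids
#'
#' Bypasses rendering and segmentation: applies the objective 3-scale (or
#' identity, for direct areas) to each participant's true A_norm grid,
#' yielding the feature set a perfect segmenter would produce. Used for
#' classifier-level experiments.
#'
#' @param config a [cohortConfig()].
#' @param kinetics a [flushKinetics()].
#' @param scheme `"three_scale"` or `"direct_area"`.
#' @param scale the [scoreScale()] for the 3-scale scheme.
#' @return an [NsrFeatureSet-class].
#' @export
generateFeatureTable <- function(config = cohortConfig(),
                                 kinetics = flushKinetics(),
                                 scheme = c("three_scale", "direct_area"),
                                 scale = scoreScale()) {
  scheme <- match.arg(scheme)
  cohort <- generateCohort(config, kinetics)
  n <- nrow(cohort$participants)
  vals <- vapply(seq_len(n), function(p)
    buildFeatureVector(cohort$aNorm[, , p], scheme, scale), numeric(20))
  NsrFeatureSet(vals, cohort$participants$id, cohort$participants$group,
                scheme)
}
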