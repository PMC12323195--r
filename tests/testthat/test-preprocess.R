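test_that("white balance maps the reference to white and is idempotent", {
  # uniform (100, 200, 50) image, reference covering all pixels:
  # gains (2.55, 1.275, 5.1) drive every pixel to pure white after clipping
  img <- flatImage(rgb = c(100, 200, 50))
  out <- whiteBalance(img, c(1, 8, 1, 12))
  expect_equal(max(abs(imagePixels(out) - 255)), 0)

  # an already-white reference leaves the image unchanged up to rounding
  img2 <- flatImage(rgb = c(180, 140, 120))
  px <- imagePixels(img2)
  px[1:3, 1:3, ] <- 255
  img2 <- NsrImage(px, "p01", 5)
  out2 <- whiteBalance(img2, c(1, 3, 1, 3))
  expect_lt(max(abs(imagePixels(out2) - px)), 1)

  # idempotence on an unsaturated image: exact to <= 1 level
  px3 <- array(0, c(10, 10, 3))
  for (ch in 1:3) px3[, , ch] <- c(120, 90, 160)[ch]
  px3[1:4, 1:4, 1] <- 200; px3[1:4, 1:4, 2] <- 180; px3[1:4, 1:4, 3] <- 220
  img3 <- NsrImage(px3, "p", 5)
  ref <- c(1, 4, 1, 4)
  once0 <- whiteBalance(img3, ref)
  twice0 <- whiteBalance(once0, ref)
  expect_lte(max(abs(imagePixels(twice0) - imagePixels(once0))), 1)

  # on a rendered photo, saturation of the corrected patch admits at most
  # a ~2-level residual (noise pixels pushed past 255 clip back)
  rend <- renderImage(c(0.15, 0.1, 0.05, 0), seed = 4)
  wr <- whiteRefFromLabel(rend$image, rend$labelMask)
  once <- whiteBalance(rend$image, wr)
  twice <- whiteBalance(once, wr)
  expect_lte(max(abs(imagePixels(twice) - imagePixels(once))), 2)
  idx <- which(maskPixels(wr))
  for (ch in 1:3)
    expect_lt(abs(mean(imagePixels(once)[, , ch][idx]) - 255), 2)
})

test_that("white balance rejects degenerate references", {
  img <- flatImage()
  expect_error(whiteBalance(img, BinaryMask(matrix(FALSE, 8, 12))), "empty")
  black <- NsrImage(array(0, c(4, 4, 3)), "p", 5)
  expect_error(whiteBalance(black, c(1, 4, 1, 4)), "zero")
})

test_that("white balance undoes a known colour cast on rendered skin", {
  cast <- c(0.75, 1.05, 1.25)
  noCast <- renderImage(c(0.15, 0.1, 0, 0), cast = c(1, 1, 1),
                        distance = 1, seed = 21)
  withCast <- renderImage(c(0.15, 0.1, 0, 0), cast = cast,
                          distance = 1, seed = 21)
  wr <- whiteRefFromLabel(withCast$image, withCast$labelMask)
  fixed <- whiteBalance(withCast$image, wr)
  skin <- !maskPixels(noCast$labelMask) & !maskPixels(noCast$flushMask)
  for (ch in 1:3) {
    ref <- mean(imagePixels(noCast$image)[, , ch][skin])
    got <- mean(imagePixels(fixed)[, , ch][skin])
    expect_lt(abs(got - ref) / ref, 0.05)
  }
})

test_that("scale calibration normalises the label to the target length", {
  rend <- renderImage(c(0.1, 0, 0, 0), distance = 1, seed = 3)
  spec <- calibrationSpec(targetLabelPx = 120)

  # label already at target -> scale 1, image untouched
  cal <- calibrateScale(rend$image, rend$labelMask, spec)
  expect_equal(cal$scale, 1)
  expect_identical(imagePixels(cal$image), imagePixels(rend$image))

  # label at half the target -> 2x linear dimensions
  half <- calibrationSpec(targetLabelPx = 240)
  cal2 <- calibrateScale(rend$image, rend$labelMask, half)
  expect_equal(cal2$scale, 2)
  expect_equal(dim(imagePixels(cal2$image))[1:2],
               2 * dim(imagePixels(rend$image))[1:2])
  expect_lte(abs(NSRscreen:::labelMajorAxisPx(cal2$labelMask) - 240), 1)

  expect_error(calibrateScale(rend$image,
                              BinaryMask(matrix(FALSE, 10, 10), "label"),
                              spec),
               "degenerate")
})

test_that("camera distance cancels out of calibrated flushing areas", {
  aN <- c(0.18, 0.12, 0.06, 0)
  areas <- lapply(c(0.9, 1.15), function(d) {
    rend <- renderImage(aN, distance = d, cast = c(1, 1, 1), seed = 5)
    pp <- preprocessImage(rend$image, rend$labelMask, rend$flushMask)
    assignSites(pp$flushMask, siteGeometry())$areas
  })
  # aggregate flushing area within 5%; per-site within 10% (the smallest
  # disc carries the largest relative rasterisation error)
  expect_lt(abs(sum(areas[[1]]) - sum(areas[[2]])) / sum(areas[[1]]), 0.05)
  for (s in 1:3)   # site 4 is empty at these settings
    expect_lt(abs(areas[[1]][s] - areas[[2]][s]) /
                max(areas[[1]][s], 1), 0.10)
})

test_that("resizing to the model grid respects interpolation rules", {
  spec <- calibrationSpec(modelInputHw = c(128L, 512L))
  px <- array(runif(128 * 512 * 3) * 255, c(128, 512, 3))
  img <- NsrImage(px, "p", 5)
  out <- resizeToInput(img, spec = spec)
  expect_identical(imagePixels(out$image), px)  # already at shape

  allTrue <- BinaryMask(matrix(TRUE, 40, 100))
  out2 <- resizeToInput(NsrImage(array(1, c(40, 100, 3)), "p", 5), allTrue,
                        spec)
  expect_true(all(maskPixels(out2$mask)))
  expect_equal(dim(maskPixels(out2$mask)), c(128L, 512L))

  # single-pixel mask upscales by roughly the pixel-area ratio
  one <- matrix(FALSE, 32, 128); one[16, 64] <- TRUE
  out3 <- resizeToInput(NsrImage(array(1, c(32, 128, 3)), "p", 5),
                        BinaryMask(one), spec)
  ratio <- (128 * 512) / (32 * 128)
  expect_gt(sum(maskPixels(out3$mask)), 0.5 * ratio)
  expect_lt(sum(maskPixels(out3$mask)), 2 * ratio)
})

test_that("augmentation is identity at zero magnitudes and reproducible", {
  rend <- renderImage(c(0.15, 0.1, 0, 0), seed = 8)
  pp <- preprocessImage(rend$image, rend$labelMask, rend$flushMask)
  none <- augmentParams(maxRotationDeg = 0, maxShiftFrac = 0,
                        scaleRange = c(1, 1), pHflip = 0, pVflip = 0,
                        brightnessDelta = 0, contrastDelta = 0,
                        saturationDelta = 0)
  out <- augmentPair(pp$image, pp$flushMask, none, drawSeed = 1)
  expect_identical(imagePixels(out$image), imagePixels(pp$image))
  expect_identical(maskPixels(out$mask), maskPixels(pp$flushMask))

  # horizontal flip is an exact involution
  flip <- augmentParams(maxRotationDeg = 0, maxShiftFrac = 0,
                        scaleRange = c(1, 1), pHflip = 1, pVflip = 0,
                        brightnessDelta = 0, contrastDelta = 0,
                        saturationDelta = 0)
  f1 <- augmentPair(pp$image, pp$flushMask, flip, drawSeed = 2)
  f2 <- augmentPair(f1$image, f1$mask, flip, drawSeed = 3)
  expect_identical(imagePixels(f2$image), imagePixels(pp$image))
  expect_identical(maskPixels(f2$mask), maskPixels(pp$flushMask))
  # flips keep image/mask alignment perfectly
  expect_equal(diceCoef(f1$mask,
                        maskPixels(pp$flushMask)[, ncol(maskPixels(pp$flushMask)):1]),
               1)

  # a fixed draw seed reproduces the augmented pair bit-for-bit
  full <- augmentParams()
  a <- augmentPair(pp$image, pp$flushMask, full, drawSeed = 99)
  b <- augmentPair(pp$image, pp$flushMask, full, drawSeed = 99)
  expect_identical(imagePixels(a$image), imagePixels(b$image))
  expect_identical(maskPixels(a$mask), maskPixels(b$mask))
  expect_true(is.logical(maskPixels(a$mask)))
  expect_equal(dim(imagePixels(a$image)), dim(imagePixels(pp$image)))
})

test_that("photometric jitter never alters the mask", {
  rend <- renderImage(c(0.15, 0.1, 0, 0), seed = 12)
  pp <- preprocessImage(rend$image, rend$labelMask, rend$flushMask)
  photo <- augmentParams(maxRotationDeg = 0, maxShiftFrac = 0,
                         scaleRange = c(1, 1), pHflip = 0, pVflip = 0,
                         brightnessDelta = 0.3, contrastDelta = 0.3,
                         saturationDelta = 0.3)
  out <- augmentPair(pp$image, pp$flushMask, photo, drawSeed = 5)
  expect_identical(maskPixels(out$mask), maskPixels(pp$flushMask))
  expect_false(identical(imagePixels(out$image), imagePixels(pp$image)))
})
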