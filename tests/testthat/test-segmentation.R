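test_that("Dice and IoU satisfy their definitions and identity", {
  # counting oracle: |P| = |G| = 100, overlap 60
  p <- matrix(FALSE, 20, 20); g <- matrix(FALSE, 20, 20)
  p[1:100] <- TRUE; g[41:140] <- TRUE
  expect_equal(diceCoef(p, g), 0.60)
  expect_equal(iouCoef(p, g), 60 / 140)
  expect_equal(diceCoef(p, g), 2 * iouCoef(p, g) / (1 + iouCoef(p, g)))

  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(diceCoef(a, a), 1)
  expect_equal(iouCoef(a, a), 1)
  b <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2)
  expect_equal(diceCoef(a, b), 0)
  expect_equal(iouCoef(a, b), 0)

  # empty-vs-empty convention and empty-vs-nonempty
  e <- matrix(FALSE, 3, 3)
  expect_equal(diceCoef(e, e), 1)
  expect_equal(iouCoef(e, e), 1)
  ne <- matrix(FALSE, 3, 3); ne[2, 2] <- TRUE
  expect_equal(diceCoef(e, ne), 0)

  expect_error(diceCoef(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shapes")
})

test_that("overlap metrics are symmetric and transform-invariant", {
  set.seed(9)
  for (i in 1:20) {
    p <- randomMask(12, 16, 0.4); g <- randomMask(12, 16, 0.3)
    d <- diceCoef(p, g); j <- iouCoef(p, g)
    expect_equal(d, diceCoef(g, p))
    expect_equal(j, iouCoef(g, p))
    expect_equal(d, 2 * j / (1 + j))
    expect_lte(j, d)
    expect_lte(d, 1)
    # simultaneous flips leave both metrics unchanged
    expect_equal(diceCoef(p[, 16:1], g[, 16:1]), d)
    expect_equal(diceCoef(p[12:1, ], g[12:1, ]), d)
  }
})

test_that("participant-level splits are proportional, disjoint and seeded", {
  ids120 <- sprintf("p%03d", 1:120)
  sp <- splitByParticipant(ids120, seed = 4)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 90L, val = 10L, test = 20L))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_setequal(unlist(sp), ids120)

  sp12 <- splitByParticipant(sprintf("q%02d", 1:12), seed = 1)
  expect_equal(lengths(sp12), c(train = 9L, val = 1L, test = 2L))

  expect_identical(splitByParticipant(ids120, seed = 7),
                   splitByParticipant(ids120, seed = 7))
  expect_false(identical(splitByParticipant(ids120, seed = 7),
                         splitByParticipant(ids120, seed = 8)))
  expect_error(splitByParticipant(c("a", "b"), seed = 1), "at least 3")

  # grouping-leakage check at the image level: every image of a participant
  # stays inside that participant's split
  imgIds <- rep(ids120, each = 5)
  for (s in names(sp))
    expect_true(all(imgIds[imgIds %in% sp[[s]]] %in% sp[[s]]))
})

test_that("model construction validates shape and emits probabilities", {
  expect_error(segModelConfig(encoderDepth = 1), "encoderDepth")
  expect_error(segModelConfig(encoderDepth = 3, inputHw = c(100, 512)),
               "divisible")
  cfg <- segModelConfig(encoderDepth = 2, baseChannels = 4,
                        inputHw = c(32L, 64L), seed = 2)
  m <- buildSegmenter(cfg)
  expect_false(m@trained)
  p <- predictProb(m, array(0, c(32, 64, 3)))
  expect_equal(dim(p), c(32L, 64L))
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  expect_error(predictProb(m, array(0, c(16, 64, 3))), "expects")

  # an untrained net is near-constant: its Dice is statistically the same
  # as the trivial all-foreground baseline on the same mask
  gt <- randomMask(32, 64, 0.2)
  dUntrained <- diceCoef(p >= 0.5, gt)
  dAllFg <- diceCoef(matrix(TRUE, 32, 64), gt)
  expect_lt(abs(dUntrained - dAllFg), 0.15)
})

test_that("probability thresholding counts the boundary as foreground", {
  expect_true(all(maskPixels(maskFromProb(matrix(0.7, 4, 4)))))
  expect_false(any(maskPixels(maskFromProb(matrix(0.3, 4, 4)))))
  expect_true(all(maskPixels(maskFromProb(matrix(0.5, 4, 4)))))  # >= rule
})

test_that("training reduces the loss and keeps the best checkpoint", {
  # small synthetic discrimination task at reduced resolution
  set.seed(6)
  mkSample <- function(i) {
    px <- array(0, c(32, 64, 3))
    px[, , 1] <- 190; px[, , 2] <- 150; px[, , 3] <- 135
    m <- matrix(FALSE, 32, 64)
    r <- 5 + (i %% 3); cy <- 10 + 3 * (i %% 4); cx <- 15 + 5 * (i %% 5)
    d2 <- outer((1:32 - cy)^2, (1:64 - cx)^2, `+`)
    m[d2 <= r^2] <- TRUE
    px[, , 1][m] <- 225; px[, , 2][m] <- 90; px[, , 3][m] <- 90
    list(img = NsrImage(px, sprintf("s%d", i), 5), mask = BinaryMask(m))
  }
  samples <- lapply(1:6, mkSample)
  cfg <- segModelConfig(encoderDepth = 2, baseChannels = 4,
                        inputHw = c(32L, 64L), lr = 3e-3, batchSize = 2,
                        epochs = 12, seed = 3)
  m <- buildSegmenter(cfg)
  tr <- trainSegmenter(m, lapply(samples, `[[`, "img"),
                       lapply(samples, `[[`, "mask"))
  expect_true(tr@trained)
  expect_equal(nrow(tr@history), 12)
  expect_true(all(is.finite(tr@history$loss)))
  expect_lt(tail(tr@history$loss, 1), tr@history$loss[1])
  # kept checkpoint attains the best recorded validation Dice
  d <- mean(vapply(samples, function(s)
    diceCoef(predictMask(tr, s$img), s$mask), numeric(1)))
  expect_equal(d, max(tr@history$valDice), tolerance = 1e-8)
  expect_gte(max(tr@history$valDice), tr@history$valDice[1])

  # empty training set and unpaired masks are rejected
  expect_error(trainSegmenter(m, list(), list()), "empty")
  expect_error(trainSegmenter(m, lapply(samples[1:2], `[[`, "img"),
                              list(samples[[1]]$mask)), "pair")
})

test_that("runtime augmentation preserves learning and generalization", {
  set.seed(6)
  mk <- function(cy, cx, r) {
    px <- array(0, c(32, 64, 3))
    px[, , 1] <- 190; px[, , 2] <- 150; px[, , 3] <- 135
    px <- px + array(rnorm(length(px), 0, 4), dim(px))
    m <- outer((1:32 - cy)^2, (1:64 - cx)^2, `+`) <= r^2
    px[, , 1][m] <- 225; px[, , 2][m] <- 90; px[, , 3][m] <- 90
    list(img = NsrImage(pmin(pmax(px, 0), 255), "s", 5),
         mask = BinaryMask(m))
  }
  train <- lapply(1:10, function(i) mk(10 + (i %% 3) * 2,
                                       12 + (i %% 5) * 3, 4 + i %% 2))
  # test blobs sit elsewhere and are larger: a shifted distribution
  test <- lapply(1:8, function(i) mk(18 + (i %% 3) * 3,
                                     38 + (i %% 4) * 5, 6 + i %% 3))
  aug <- augmentParams(maxRotationDeg = 8, maxShiftFrac = 0.12,
                       scaleRange = c(0.85, 1.2), pHflip = 0.5,
                       pVflip = 0.5, brightnessDelta = 0.1,
                       contrastDelta = 0.1, saturationDelta = 0.1)
  cfg <- segModelConfig(2, 4, c(32L, 64L), lr = 3e-3, batchSize = 2,
                        epochs = 30, seed = 3)
  evalD <- function(m, set) mean(vapply(set, function(s)
    diceCoef(predictMask(m, s$img), s$mask), numeric(1)))
  mPlain <- trainSegmenter(buildSegmenter(cfg),
                           lapply(train, `[[`, "img"),
                           lapply(train, `[[`, "mask"))
  mAug <- trainSegmenter(buildSegmenter(cfg), lapply(train, `[[`, "img"),
                         lapply(train, `[[`, "mask"), augment = aug)
  # augmentation must not materially hurt fit or transfer
  expect_gte(evalD(mAug, train), evalD(mPlain, train) - 0.05)
  expect_gte(evalD(mAug, test), evalD(mPlain, test) - 0.05)
  expect_gte(evalD(mAug, test), 0.85)
})

test_that("checkpoints round-trip through save/load", {
  cfg <- segModelConfig(encoderDepth = 2, baseChannels = 4,
                        inputHw = c(32L, 64L), seed = 8)
  m <- buildSegmenter(cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  saveSegmenter(m, path)
  m2 <- loadSegmenter(path)
  expect_identical(m2@weights, m@weights)
  expect_identical(m2@config, m@config)
  x <- array(runif(32 * 64 * 3) * 255, c(32, 64, 3))
  expect_identical(predictProb(m, x), predictProb(m2, x))
})
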