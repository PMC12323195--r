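#' @include AllGenerics.R
NULL

#' Configuration for the flushing-area segmentation network
#'
#' The segmenter is a plain U-Net: `encoderDepth` down-sampling stages of two
#' 3x3 ReLU convolutions each, a bottleneck, mirrored decoder stages with
#' nearest-neighbour upsampling and skip concatenation, and a 1x1 sigmoid
#' head producing a per-pixel flushing probability. Trained with a combined
#' soft-dice + binary cross-entropy loss under Adam.
#'
#' @param encoderDepth number of down-sampling stages (>= 2).
#' @param baseChannels channels of the first stage; doubled per stage.
#' @param inputHw input (height, width); both must be divisible by
#'   `2^encoderDepth`. Default `c(128, 512)`, the calibrated model shape.
#' @param loss `"dice+bce"` (default), `"bce"` or `"dice"`.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batchSize mini-batch size.
#' @param seed run seed controlling weight init, shuffling and augmentation.
#' @return a `SegModelConfig` list.
#' @export
segModelConfig <- function(encoderDepth = 2, baseChannels = 8,
                           inputHw = c(128L, 512L),
                           loss = c("dice+bce", "bce", "dice"),
                           lr = 1e-3, epochs = 10, batchSize = 8, seed = 1) {
  loss <- match.arg(loss)
  encoderDepth <- as.integer(encoderDepth)
  if (encoderDepth < 2) stop("encoderDepth must be >= 2")
  inputHw <- as.integer(inputHw)
  if (any(inputHw %% 2^encoderDepth != 0))
    stop("input dimensions must be divisible by 2^encoderDepth")
  structure(list(encoderDepth = encoderDepth,
                 baseChannels = as.integer(baseChannels),
                 inputHw = inputHw, loss = loss, lr = lr,
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 seed = as.integer(seed)),
            class = "SegModelConfig")
}

# Channel plan for each conv, in forward order; used for init and checks.
unetConvPlan <- function(depth, base) {
  ch <- base * 2^(0:(depth))          # stage channels; last = bottleneck
  plan <- list()
  inc <- 3L
  for (l in seq_len(depth)) {         # encoder
    plan[[length(plan) + 1L]] <- c(inc, ch[l], 3L)
    plan[[length(plan) + 1L]] <- c(ch[l], ch[l], 3L)
    inc <- ch[l]
  }
  plan[[length(plan) + 1L]] <- c(ch[depth], ch[depth + 1L], 3L)
  plan[[length(plan) + 1L]] <- c(ch[depth + 1L], ch[depth + 1L], 3L)
  up <- ch[depth + 1L]
  for (l in rev(seq_len(depth))) {    # decoder
    plan[[length(plan) + 1L]] <- c(up + ch[l], ch[l], 3L)
    plan[[length(plan) + 1L]] <- c(ch[l], ch[l], 3L)
    up <- ch[l]
  }
  plan[[length(plan) + 1L]] <- c(ch[1L], 1L, 1L)  # output head
  plan
}

#' Build an untrained segmentation model
#'
#' Initialises U-Net weights (He initialisation, seeded from the config) and
#' returns an [NsrSegmenter-class] handle.
#'
#' @param config a [segModelConfig()].
#' @return an [NsrSegmenter-class].
#' @export
#' @examples
#' m <- buildSegmenter(segModelConfig(encoderDepth = 2, baseChannels = 4,
#'                                    inputHw = c(32, 64)))
#' m
buildSegmenter <- function(config = segModelConfig()) {
  plan <- unetConvPlan(config$encoderDepth, config$baseChannels)
  weights <- withSeed(config$seed, {
    w <- list()
    for (i in seq_along(plan)) {
      cin <- plan[[i]][1]; cout <- plan[[i]][2]; k <- plan[[i]][3]
      fan <- k * k * cin
      w[[2 * i - 1]] <- matrix(rnorm(cout * fan, sd = sqrt(2 / fan)),
                               cout, fan)
      w[[2 * i]] <- rep(0, cout)
    }
    w
  })
  new("NsrSegmenter", weights = weights, config = unclass(config),
      trained = FALSE, history = data.frame())
}

asPixelArray <- function(image) {
  if (is(image, "NsrImage")) imagePixels(image) else image
}
asMaskMatrix <- function(mask) {
  if (is(mask, "BinaryMask")) maskPixels(mask) else mask != 0
}

checkInputShape <- function(model, px) {
  hw <- model@config$inputHw
  if (!all(dim(px)[1:2] == hw))
    stop(sprintf("image is %dx%d but the model expects %dx%d",
                 dim(px)[1], dim(px)[2], hw[1], hw[2]))
}

#' Predict the per-pixel flushing probability map
#'
#' @param model a (trained) [NsrSegmenter-class].
#' @param image an [NsrImage-class] or `H x W x 3` array at the model input
#'   shape.
#' @return numeric `H x W` matrix of probabilities in `[0, 1]`.
#' @export
predictProb <- function(model, image) {
  px <- asPixelArray(image)
  checkInputShape(model, px)
  unet_predict_cpp(model@weights, px / 255, model@config$encoderDepth)
}

#' Threshold a probability map into a flushing mask
#'
#' Pixels with probability `>= threshold` are foreground (the boundary value
#' counts as flushing). No morphological post-processing is applied.
#'
#' @param prob numeric probability matrix.
#' @param threshold decision threshold, default 0.5.
#' @return a [BinaryMask-class] of kind `"flush"`.
#' @export
maskFromProb <- function(prob, threshold = 0.5) {
  BinaryMask(prob >= threshold, kind = "flush")
}

#' Predict a binary flushing mask for a calibrated image
#'
#' @inheritParams predictProb
#' @param threshold decision threshold (>= counts as foreground).
#' @return a [BinaryMask-class].
#' @export
predictMask <- function(model, image, threshold = 0.5) {
  maskFromProb(predictProb(model, image), threshold)
}

#' Train the segmentation network
#'
#' Adam optimisation of the configured loss, with optional paired runtime
#' augmentation of each training sample, per-epoch validation Dice, and
#' selection of the checkpoint with the best validation Dice (training Dice
#' when no validation set is given). Aborts if the loss goes non-finite.
#'
#' @param model an [NsrSegmenter-class] from [buildSegmenter()].
#' @param trainImages,trainMasks lists of images and paired flushing masks.
#' @param valImages,valMasks optional validation pairs.
#' @param augment optional [augmentParams()] applied per sample per epoch.
#' @param epochs overrides the config epoch count when given.
#' @return the trained [NsrSegmenter-class] with a populated `history`.
#' @export
trainSegmenter <- function(model, trainImages, trainMasks,
                           valImages = NULL, valMasks = NULL,
                           augment = NULL, epochs = NULL) {
  cfg <- model@config
  if (length(trainImages) == 0L) stop("empty training set")
  if (length(trainImages) != length(trainMasks))
    stop("images and masks must pair up")
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  wBce <- if (cfg$loss == "dice") 0 else 1
  wDice <- if (cfg$loss == "bce") 0 else 1

  xs <- lapply(trainImages, asPixelArray)
  gs <- lapply(trainMasks, asMaskMatrix)
  for (x in xs) checkInputShape(model, x)

  weights <- model@weights
  mAdam <- lapply(weights, function(w) w * 0)
  vAdam <- lapply(weights, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  tStep <- 0L

  evalDice <- function(w, imgs, msks) {
    d <- mapply(function(im, mk) {
      p <- unet_predict_cpp(w, asPixelArray(im) / 255, cfg$encoderDepth)
      diceCoef(p >= 0.5, asMaskMatrix(mk))
    }, imgs, msks)
    mean(d)
  }

  bestWeights <- weights
  bestVal <- -Inf
  hist <- NULL

  withSeed(cfg$seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(xs))
      epLoss <- 0
      nb <- 0L
      for (start in seq(1, length(ord), by = cfg$batchSize)) {
        bidx <- ord[start:min(start + cfg$batchSize - 1L, length(ord))]
        gsum <- NULL
        bl <- 0
        for (i in bidx) {
          xi <- xs[[i]]; gi <- gs[[i]]
          if (!is.null(augment)) {
            pair <- augmentPair(NsrImage(xi, "aug", 1L),
                                BinaryMask(gi), augment,
                                drawSeed = sample.int(2^30, 1))
            xi <- imagePixels(pair$image); gi <- maskPixels(pair$mask)
          }
          step <- unet_train_step_cpp(weights, xi / 255, gi * 1,
                                      cfg$encoderDepth, wBce, wDice)
          if (!is.finite(step$loss))
            stop(sprintf("non-finite loss at epoch %d (sample %d); %s",
                         ep, i, "lower the learning rate"))
          bl <- bl + step$loss
          if (is.null(gsum)) gsum <- step$grads
          else gsum <- mapply(`+`, gsum, step$grads, SIMPLIFY = FALSE)
        }
        gsum <- lapply(gsum, function(g) g / length(bidx))
        tStep <- tStep + 1L
        for (j in seq_along(weights)) {
          mAdam[[j]] <- b1 * mAdam[[j]] + (1 - b1) * gsum[[j]]
          vAdam[[j]] <- b2 * vAdam[[j]] + (1 - b2) * gsum[[j]]^2
          mh <- mAdam[[j]] / (1 - b1^tStep)
          vh <- vAdam[[j]] / (1 - b2^tStep)
          weights[[j]] <- weights[[j]] - cfg$lr * mh / (sqrt(vh) + epsA)
        }
        epLoss <- epLoss + bl / length(bidx)
        nb <- nb + 1L
      }
      vd <- if (!is.null(valImages) && length(valImages) > 0)
        evalDice(weights, valImages, valMasks)
      else evalDice(weights, xs, gs)
      hist <- rbind(hist, data.frame(epoch = ep, loss = epLoss / nb,
                                     valDice = vd))
      if (vd >= bestVal) { bestVal <- vd; bestWeights <- weights }
    }
  })

  new("NsrSegmenter", weights = bestWeights, config = cfg, trained = TRUE,
      history = hist)
}

#' Save / load a segmentation model checkpoint
#'
#' A checkpoint is a single RDS file carrying the weights, the config echo,
#' and the training history.
#'
#' @param model an [NsrSegmenter-class].
#' @param path file path.
#' @return `loadSegmenter` returns the [NsrSegmenter-class].
#' @export
saveSegmenter <- function(model, path) {
  saveRDS(list(weights = model@weights, config = model@config,
               trained = model@trained, history = model@history), path)
  invisible(path)
}

#' @rdname saveSegmenter
#' @export
loadSegmenter <- function(path) {
  x <- readRDS(path)
  new("NsrSegmenter", weights = x$weights, config = x$config,
      trained = x$trained, history = x$history)
}

#' Dice and IoU overlap metrics
#'
#' `diceCoef` is `2|P.G| / (|P| + |G|)`; `iouCoef` is `|P.G| / |P u G|`.
#' Two empty masks compare as 1; an empty vs a non-empty mask as 0. The two
#' are linked by `dice = 2 iou / (1 + iou)` on any single mask pair.
#'
#' @param pred,gt [BinaryMask-class] objects or logical matrices of equal
#'   shape.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' diceCoef(a, a)
diceCoef <- function(pred, gt) {
  p <- asMaskMatrix(pred); g <- asMaskMatrix(gt)
  if (!all(dim(p) == dim(g))) stop("mask shapes differ")
  s <- sum(p) + sum(g)
  if (s == 0) return(1)
  2 * sum(p & g) / s
}

#' @rdname diceCoef
#' @export
iouCoef <- function(pred, gt) {
  p <- asMaskMatrix(pred); g <- asMaskMatrix(gt)
  if (!all(dim(p) == dim(g))) stop("mask shapes differ")
  u <- sum(p | g)
  if (u == 0) return(1)
  sum(p & g) / u
}

#' Patient-level train/validation/test split
#'
#' Partitions participant ids into train/validation/test sets in the given
#' proportions (default 90/10/20 of a 120-participant cohort, scaled
#' proportionally for other cohort sizes), so that every image of a
#' participant lands in that participant's set. Deterministic given `seed`.
#'
#' @param ids character vector of participant ids (duplicates collapsed).
#' @param fractions relative sizes of train/validation/test.
#' @param seed RNG seed.
#' @return list with `train`, `val`, `test` id vectors.
#' @export
#' @examples
#' splitByParticipant(sprintf("p%03d", 1:12), seed = 7)
splitByParticipant <- function(ids, fractions = c(90, 10, 20), seed = 1) {
  ids <- unique(as.character(ids))
  n <- length(ids)
  if (n < 3) stop("need at least 3 participants to split")
  frac <- fractions / sum(fractions)
  sizes <- floor(n * frac)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(n * frac - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  shuffled <- withSeed(seed, sample(ids))
  bounds <- cumsum(sizes)
  list(train = sort(shuffled[seq_len(bounds[1])]),
       val = sort(shuffled[seq_len(bounds[2])[-seq_len(bounds[1])]]),
       test = sort(shuffled[-seq_len(bounds[2])]))
}
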