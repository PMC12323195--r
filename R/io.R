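#' @include AllClasses.R
NULL

#' Declarative dataset layout
#'
#' The on-disk layout of an NSR dataset: subdirectories for photographs,
#' flushing masks and (optionally) arm-label masks, a filename pattern with
#' named capture groups `participant` and `time`, a template used when
#' writing, and the name of the info table. The default matches the layout
#' emitted by [writeNsrDataset()]: `images/<id>_t<mm>.png`,
#' `masks/<id>_t<mm>.png`, `labels/<id>_t<mm>.png`, `info.csv`. The naming
#' convention of externally deposited datasets is not standardised, hence
#' this config rather than hard-wired paths.
#'
#' @param imageDir,maskDir,labelMaskDir subdirectory names; set
#'   `labelMaskDir = NA` when no label masks exist.
#' @param pattern PCRE with named groups `participant` and `time`.
#' @param template `sprintf` template for writing (`id`, `time`).
#' @param infoFile CSV file name, or `NA` for none.
#' @return an `NsrLayout` list.
#' @export
nsrLayout <- function(imageDir = "images", maskDir = "masks",
                      labelMaskDir = "labels",
                      pattern = "^(?<participant>.+)_t(?<time>[0-9]+)\\.(png|jpg|jpeg)$",
                      template = "%s_t%02d.png",
                      infoFile = "info.csv") {
  structure(list(imageDir = imageDir, maskDir = maskDir,
                 labelMaskDir = labelMaskDir, pattern = pattern,
                 template = template, infoFile = infoFile),
            class = "NsrLayout")
}

parseFileName <- function(fname, pattern) {
  m <- regexpr(pattern, fname, perl = TRUE, ignore.case = TRUE)
  if (m == -1L) return(NULL)
  st <- attr(m, "capture.start")[1, ]
  len <- attr(m, "capture.length")[1, ]
  grab <- function(g) substr(fname, st[[g]], st[[g]] + len[[g]] - 1L)
  list(participant = grab("participant"), time = as.integer(grab("time")))
}

readImageFile <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
    if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
    round(a * 255)  # sources are 8-bit; keeps round trips exact
  } else {
    round(fromEB(EBImage::readImage(path)))
  }
}

#' Read and write binary mask files
#'
#' Masks are stored as single-channel 8-bit PNGs with 0 = background and
#' 255 = foreground; on reading, any nonzero value counts as foreground
#' (tolerant of annotation-tool exports). Round trips are bit-exact.
#'
#' @param path file path.
#' @param kind mask kind for the returned object.
#' @return `readMask` returns a [BinaryMask-class].
#' @export
readMask <- function(path, kind = "flush") {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  BinaryMask(a != 0, kind = kind)
}

#' @rdname readMask
#' @param mask a [BinaryMask-class] or logical matrix.
#' @export
writeMask <- function(mask, path) {
  m <- if (is(mask, "BinaryMask")) maskPixels(mask) else mask
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Write a set of masks to a directory
#'
#' @param masks named list of [BinaryMask-class] objects (names become file
#'   names, `.png` appended when absent).
#' @param outPath output directory, created if needed.
#' @return invisibly, the written paths.
#' @export
writeMasks <- function(masks, outPath) {
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("masks must be a named list")
  dir.create(outPath, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outPath)) stop("cannot create directory: ", outPath)
  paths <- file.path(outPath, ifelse(grepl("\\.png$", names(masks)),
                                     names(masks),
                                     paste0(names(masks), ".png")))
  for (i in seq_along(masks)) writeMask(masks[[i]], paths[i])
  invisible(paths)
}

#' Multi-annotator consensus mask
#'
#' A pixel belongs to the consensus flushing area if and only if at least
#' `minVotes` annotators marked it (default 2, the rule used to consolidate
#' five independent annotations into ground truth). `minVotes = 1` is the
#' union of the annotations, `minVotes = length(masks)` their intersection.
#'
#' @param masks list of [BinaryMask-class] objects (or logical matrices) of
#'   identical shape.
#' @param minVotes minimum number of annotators marking a pixel.
#' @return a [BinaryMask-class].
#' @export
#' @examples
#' m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' m2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
#' maskPixels(consensusMask(list(m1, m2), minVotes = 2))
consensusMask <- function(masks, minVotes = 2) {
  if (length(masks) < 1) stop("need at least one annotator mask")
  ms <- lapply(masks, function(m)
    if (is(m, "BinaryMask")) maskPixels(m) else m != 0)
  d <- dim(ms[[1]])
  for (m in ms) if (!all(dim(m) == d)) stop("annotator mask shapes differ")
  if (minVotes < 1 || minVotes > length(ms))
    stop("minVotes must be between 1 and the number of masks")
  votes <- Reduce(`+`, ms)
  kind <- if (is(masks[[1]], "BinaryMask")) maskKind(masks[[1]]) else "flush"
  BinaryMask(votes >= minVotes, kind = kind)
}

validateInfoRow <- function(row, i) {
  if (!(row$group %in% NSR_GROUPS))
    stop(sprintf("info row %d: group '%s' is not one of %s", i, row$group,
                 paste(NSR_GROUPS, collapse = "/")), call. = FALSE)
  if (is.na(row$time_min) || !(row$time_min %in% NSR_TIMES))
    stop(sprintf("info row %d: time_min must be one of %s", i,
                 paste(NSR_TIMES, collapse = ",")), call. = FALSE)
  sc <- unlist(row[grep("^score_", names(row))])
  if (anyNA(sc) || !all(sc %in% 0:3))
    stop(sprintf("info row %d: manual scores must be integers 0-3", i),
         call. = FALSE)
  invisible(TRUE)
}

#' Read an NSR dataset from disk
#'
#' Reads photographs, their paired flushing masks, optional arm-label masks
#' and the info table, joining everything on `(participant, time)` parsed
#' from the file names via the layout pattern. Every image must have a
#' flushing mask of the same file name; a missing mask is a hard error
#' naming the file.
#'
#' @param root dataset root directory.
#' @param layout an [nsrLayout()].
#' @param verbose log counts.
#' @return list with `images` (list of [NsrImage-class]), `flushMasks`,
#'   `labelMasks` (lists of [BinaryMask-class], the latter possibly empty)
#'   and `info` (`data.frame`, zero rows when absent).
#' @export
readNsrDataset <- function(root, layout = nsrLayout(), verbose = FALSE) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  imgDir <- file.path(root, layout$imageDir)
  files <- if (dir.exists(imgDir)) sort(list.files(imgDir)) else character()
  images <- list(); flushMasks <- list(); labelMasks <- list()
  for (f in files) {
    meta <- parseFileName(f, layout$pattern)
    if (is.null(meta)) next
    mpath <- file.path(root, layout$maskDir, f)
    if (!file.exists(mpath))
      stop("missing flushing mask for image: ", f)
    img <- NsrImage(readImageFile(file.path(imgDir, f)), meta$participant,
                    meta$time, sourcePath = file.path(imgDir, f))
    key <- sprintf("%s_t%02d", meta$participant, meta$time)
    images[[key]] <- img
    flushMasks[[key]] <- readMask(mpath, kind = "flush")
    if (!is.na(layout$labelMaskDir)) {
      lpath <- file.path(root, layout$labelMaskDir, f)
      if (file.exists(lpath)) labelMasks[[key]] <- readMask(lpath, "label")
    }
  }
  info <- data.frame()
  if (!is.na(layout$infoFile) &&
      file.exists(file.path(root, layout$infoFile))) {
    info <- read.csv(file.path(root, layout$infoFile),
                     stringsAsFactors = FALSE, check.names = FALSE)
    for (i in seq_len(nrow(info))) validateInfoRow(info[i, ], i)
  }
  if (verbose)
    message(sprintf("read %d images, %d flush masks, %d label masks, %d info rows",
                    length(images), length(flushMasks), length(labelMasks),
                    nrow(info)))
  list(images = images, flushMasks = flushMasks, labelMasks = labelMasks,
       info = info)
}

#' Write an NSR dataset to disk
#'
#' Writes the in-memory dataset (as returned by [generateSyntheticDataset()]
#' or [readNsrDataset()]) in the layout's directory structure. Images and
#' masks are written as PNG; the info table as CSV.
#'
#' @param dataset list with `images`, `flushMasks`, optional `labelMasks`
#'   and `info`.
#' @param root output root directory.
#' @param layout an [nsrLayout()].
#' @return invisibly, `root`.
#' @export
writeNsrDataset <- function(dataset, root, layout = nsrLayout()) {
  for (d in c(layout$imageDir, layout$maskDir,
              if (!is.na(layout$labelMaskDir) &&
                  length(dataset$labelMasks)) layout$labelMaskDir))
    dir.create(file.path(root, d), showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(root)) stop("cannot create dataset root: ", root)
  for (key in names(dataset$images)) {
    img <- dataset$images[[key]]
    fname <- sprintf(layout$template, participantId(img), timeMin(img))
    png::writePNG(imagePixels(img) / 255,
                  file.path(root, layout$imageDir, fname))
    writeMask(dataset$flushMasks[[key]],
              file.path(root, layout$maskDir, fname))
    if (length(dataset$labelMasks) && !is.null(dataset$labelMasks[[key]]))
      writeMask(dataset$labelMasks[[key]],
                file.path(root, layout$labelMaskDir, fname))
  }
  if (!is.null(dataset$info) && nrow(dataset$info) > 0 &&
      !is.na(layout$infoFile))
    write.csv(dataset$info, file.path(root, layout$infoFile),
              row.names = FALSE, quote = FALSE)
  invisible(root)
}
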