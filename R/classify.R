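#' @include AllClasses.R
NULL

#' SMOTE configuration
#'
#' @param kNeighbors number of minority-class nearest neighbours to
#'   interpolate towards (must be smaller than the minority class size).
#' @param seed RNG seed for the interpolation draws.
#' @return a `SmoteConfig` list.
#' @export
smoteConfig <- function(kNeighbors = 5, seed = NULL) {
  structure(list(kNeighbors = as.integer(kNeighbors), seed = seed),
            class = "SmoteConfig")
}

#' SMOTE minority oversampling
#'
#' Canonical SMOTE: synthetic minority samples are drawn as
#' `x_i + u (x_nn - x_i)` with `u ~ Uniform(0, 1)` and `x_nn` one of the
#' `kNeighbors` nearest minority neighbours of `x_i` (Euclidean distance),
#' until the two classes have equal counts. Original samples are preserved;
#' already-balanced input is returned unchanged. Intended to run strictly
#' inside a training fold, never on held-out data.
#'
#' @param X numeric matrix (samples x features).
#' @param y two-level factor (or vector coercible to one).
#' @param config a [smoteConfig()].
#' @return list with oversampled `X` and `y`.
#' @export
smoteOversample <- function(X, y, config = smoteConfig()) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("smoteOversample expects exactly two classes")
  counts <- table(y)
  if (counts[1] == counts[2]) return(list(X = X, y = y))
  minority <- names(counts)[which.min(counts)]
  mIdx <- which(y == minority)
  m <- length(mIdx)
  k <- config$kNeighbors
  if (k >= m)
    stop(sprintf("minority class has %d samples; choose kNeighbors < %d", m, m))
  nSynth <- max(counts) - m
  Xm <- X[mIdx, , drop = FALSE]
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  nnl <- apply(D, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1) matrix(nnl, ncol = 1) else t(nnl)
  synth <- withSeed(config$seed, {
    base <- sample(rep_len(seq_len(m), nSynth))
    t(vapply(base, function(i) {
      j <- nn[i, sample.int(k, 1)]
      u <- runif(1)
      Xm[i, ] + u * (Xm[j, ] - Xm[i, ])
    }, numeric(ncol(X))))
  })
  list(X = rbind(X, synth),
       y = factor(c(as.character(y), rep(minority, nSynth)),
                  levels = levels(y)))
}

#' Hyperparameter grid for the screening SVM
#'
#' The searched grid: RBF kernel over `C x gamma`, polynomial kernel over
#' `C x degree`, each crossed with the SMOTE neighbour counts. Combinations
#' are enumerated in a fixed order; grid-search ties resolve to the first
#' listed combination.
#'
#' @param kernels subset of `c("rbf", "poly")`.
#' @param C regularization values.
#' @param gamma RBF kernel widths.
#' @param degree polynomial degrees.
#' @param smoteK SMOTE `kNeighbors` values.
#' @return a `HyperGrid` list.
#' @export
hyperGrid <- function(kernels = c("rbf", "poly"), C = c(0.1, 1, 10),
                      gamma = c(0.01, 0.1, 1), degree = c(2, 3, 4),
                      smoteK = c(3, 5, 7)) {
  kernels <- match.arg(kernels, several.ok = TRUE)
  structure(list(kernels = kernels, C = C, gamma = gamma, degree = degree,
                 smoteK = smoteK), class = "HyperGrid")
}

expandHyperGrid <- function(grid) {
  out <- NULL
  if ("rbf" %in% grid$kernels)
    out <- rbind(out, expand.grid(kernel = "rbf", C = grid$C,
                                  gamma = grid$gamma, degree = NA,
                                  smoteK = grid$smoteK,
                                  stringsAsFactors = FALSE))
  if ("poly" %in% grid$kernels)
    out <- rbind(out, expand.grid(kernel = "poly", C = grid$C, gamma = NA,
                                  degree = grid$degree,
                                  smoteK = grid$smoteK,
                                  stringsAsFactors = FALSE))
  out
}

#' Cross-validation configuration
#'
#' @param nFolds outer folds (default 5: 80% train / 20% test per fold).
#' @param innerFolds folds of the nested grid-search CV on each training
#'   portion.
#' @param stratified preserve class proportions per fold.
#' @param standardize fit zero-mean/unit-variance scaling on each training
#'   portion (applied before SMOTE and to the held-out fold).
#' @param seed RNG seed for fold assignment and SMOTE draws.
#' @return a `CvConfig` list.
#' @export
cvConfig <- function(nFolds = 5, innerFolds = 3, stratified = TRUE,
                     standardize = TRUE, seed = 1) {
  if (nFolds < 2) stop("nFolds must be >= 2")
  structure(list(nFolds = as.integer(nFolds),
                 innerFolds = as.integer(innerFolds),
                 stratified = stratified, standardize = standardize,
                 seed = as.integer(seed)), class = "CvConfig")
}

stratifiedFolds <- function(y, k, seed) {
  folds <- vector("list", k)
  withSeed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      bins <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[bins == f])
    }
  })
  lapply(folds, sort)
}

#' Metrics from a pooled 2x2 confusion matrix
#'
#' Rows are actual classes (HC first, patient second), columns predicted in
#' the same order. Sensitivity is the patient-class recall, specificity the
#' HC recall, balanced accuracy their mean, overall accuracy the trace over
#' the total; precision/recall/F1 are reported per class.
#'
#' @param cm 2x2 nonnegative matrix with positive row sums.
#' @return named list: `sensitivity`, `specificity`, `balancedAccuracy`,
#'   `overallAccuracy`, `precision`, `recall`, `f1` (two-element vectors
#'   named HC/patient).
#' @export
#' @examples
#' metricsFromConfusion(matrix(c(45, 8, 15, 12), 2))
metricsFromConfusion <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(2, 2))) stop("confusion matrix must be 2x2")
  if (any(cm < 0)) stop("confusion entries must be nonnegative")
  rs <- rowSums(cm)
  if (any(rs == 0)) stop("each actual class must have at least one sample")
  cls <- rownames(cm)
  if (is.null(cls)) cls <- c("HC", "patient")
  sens <- cm[2, 2] / rs[2]
  spec <- cm[1, 1] / rs[1]
  cs <- colSums(cm)
  prec <- ifelse(cs > 0, diag(cm) / cs, NA_real_)
  rec <- diag(cm) / rs
  f1 <- ifelse(is.na(prec) | prec + rec == 0, NA_real_,
               2 * prec * rec / (prec + rec))
  names(prec) <- names(rec) <- names(f1) <- cls
  list(sensitivity = unname(sens), specificity = unname(spec),
       balancedAccuracy = unname((sens + spec) / 2),
       overallAccuracy = sum(diag(cm)) / sum(cm),
       precision = prec, recall = rec, f1 = f1)
}

balancedAccFromPreds <- function(truth, pred, patientLevel) {
  sens <- mean(pred[truth == patientLevel] == patientLevel)
  spec <- mean(pred[truth != patientLevel] != patientLevel)
  (sens + spec) / 2
}

fitSvm <- function(X, y, combo) {
  if (combo$kernel == "rbf")
    e1071::svm(X, y, kernel = "radial", cost = combo$C, gamma = combo$gamma,
               scale = FALSE)
  else
    e1071::svm(X, y, kernel = "polynomial", cost = combo$C,
               degree = combo$degree, gamma = 1 / ncol(X), coef0 = 1,
               scale = FALSE)
}

#' Cross-validated SMOTE + SVM screening
#'
#' The full screening harness for one binary comparison (HC vs. one
#' disorder): stratified `nFolds`-fold outer cross-validation; within each
#' training portion, features are standardized, SMOTE balances the classes,
#' and a grid search (nested stratified inner CV, selection by balanced
#' accuracy, first-listed combination winning ties) picks the SVM
#' hyperparameters; the refit model predicts the untouched held-out 20%.
#' Out-of-fold predictions are pooled into a single confusion matrix from
#' which all metrics derive. SMOTE and scaling never see held-out samples;
#' an internal guard aborts on any train/test index overlap.
#'
#' @param features an [NsrFeatureSet-class], or a samples-x-features matrix.
#' @param comparison e.g. `"HC vs DP"`; required for an `NsrFeatureSet`
#'   containing more than two groups. Ignored when `labels` is given.
#' @param labels two-level factor (HC level first) when `features` is a
#'   plain matrix.
#' @param grid a [hyperGrid()].
#' @param cv a [cvConfig()].
#' @return a [ScreeningResult-class].
#' @export
runScreening <- function(features, comparison = NULL, labels = NULL,
                         grid = hyperGrid(), cv = cvConfig()) {
  if (is(features, "NsrFeatureSet")) {
    groups <- as.character(groupLabels(features))
    if (is.null(comparison)) {
      present <- unique(groups)
      if (length(present) != 2)
        stop("comparison must be given for a multi-group feature set")
      patient <- setdiff(present, "HC")
    } else {
      patient <- sub("^HC\\s+vs\\.?\\s+", "", comparison)
      if (!patient %in% NSR_GROUPS || patient == "HC")
        stop("comparison must be of the form 'HC vs DP|BP|SZ'")
    }
    keep <- groups %in% c("HC", patient)
    X <- featureMatrix(features)[keep, , drop = FALSE]
    y <- factor(groups[keep], levels = c("HC", patient))
    scheme <- featureScheme(features)
  } else {
    X <- as.matrix(features)
    if (is.null(labels)) stop("labels are required for a plain matrix")
    y <- factor(labels)
    if (nlevels(y) != 2) stop("labels must have exactly two levels")
    patient <- levels(y)[2]
    scheme <- "custom"
  }
  if (any(table(y) < cv$nFolds))
    stop("each class needs at least nFolds samples")
  combos <- expandHyperGrid(grid)
  outer <- stratifiedFolds(y, cv$nFolds, cv$seed)

  pooledTruth <- character(0); pooledPred <- character(0)
  bestParams <- vector("list", cv$nFolds)

  for (f in seq_len(cv$nFolds)) {
    testIdx <- outer[[f]]
    trainIdx <- setdiff(seq_along(y), testIdx)
    if (length(intersect(trainIdx, testIdx)) > 0)
      stop("leakage guard: train/test overlap")  # unreachable by design
    Xtr <- X[trainIdx, , drop = FALSE]; ytr <- y[trainIdx]
    Xte <- X[testIdx, , drop = FALSE]
    if (cv$standardize) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, sd); sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    inner <- stratifiedFolds(ytr, cv$innerFolds, subSeed(cv$seed, f))
    comboScore <- numeric(nrow(combos))
    for (ci in seq_len(nrow(combos))) {
      combo <- combos[ci, ]
      truthI <- character(0); predI <- character(0)
      for (g in seq_len(cv$innerFolds)) {
        vIdx <- inner[[g]]
        tIdx <- setdiff(seq_along(ytr), vIdx)
        sm <- smoteOversample(Xtr[tIdx, , drop = FALSE], ytr[tIdx],
                              smoteConfig(combo$smoteK,
                                          subSeed(cv$seed, 100 * f + g)))
        fit <- fitSvm(sm$X, sm$y, combo)
        predI <- c(predI, as.character(predict(fit,
                                               Xtr[vIdx, , drop = FALSE])))
        truthI <- c(truthI, as.character(ytr[vIdx]))
      }
      comboScore[ci] <- balancedAccFromPreds(truthI, predI, patient)
    }
    best <- which.max(comboScore)  # first max wins ties
    bestParams[[f]] <- c(as.list(combos[best, ]),
                         innerBalancedAccuracy = comboScore[best])
    sm <- smoteOversample(Xtr, ytr,
                          smoteConfig(combos$smoteK[best],
                                      subSeed(cv$seed, 1000 + f)))
    fit <- fitSvm(sm$X, sm$y, combos[best, ])
    pooledPred <- c(pooledPred, as.character(predict(fit, Xte)))
    pooledTruth <- c(pooledTruth, as.character(y[testIdx]))
  }

  cm <- table(factor(pooledTruth, levels = levels(y)),
              factor(pooledPred, levels = levels(y)))
  cm <- matrix(as.integer(cm), 2, 2,
               dimnames = list(actual = levels(y), predicted = levels(y)))
  new("ScreeningResult",
      comparison = paste("HC vs", patient), scheme = scheme,
      confusion = cm, metrics = metricsFromConfusion(cm),
      bestParams = bestParams, nFolds = cv$nFolds)
}

#' Score-threshold baseline screening
#'
#' The classical single-score rule: a participant is predicted to be a
#' patient when their NSR score at the given concentration and time falls
#' below `cutoff` (an attenuated flushing response).
#'
#' @param features a three-scale [NsrFeatureSet-class].
#' @param concentration one of 0.1, 0.01, 0.001, 0.0001 (M).
#' @param timeMin one of 1, 5, 10, 15, 20.
#' @param cutoff predict patient iff score < cutoff.
#' @return factor of predictions with levels `c("HC", "patient")`.
#' @export
baselineScoreClassifier <- function(features, concentration, timeMin,
                                    cutoff = 2) {
  ord <- featureOrdering()
  row <- which(ord$concentration == concentration & ord$timeMin == timeMin)
  if (length(row) != 1)
    stop(sprintf("no score at (%s M, %s min)", concentration, timeMin))
  sc <- SummarizedExperiment::assay(features, "features")[row, ]
  factor(ifelse(sc < cutoff, "patient", "HC"), levels = c("HC", "patient"))
}

#' Total NSR score per participant
#'
#' Sum of all 20 concentration-by-time scores, the classical aggregate
#' response measure.
#'
#' @param features a three-scale [NsrFeatureSet-class].
#' @return named numeric vector (one total per participant).
#' @export
totalScore <- function(features) {
  colSums(SummarizedExperiment::assay(features, "features"))
}
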