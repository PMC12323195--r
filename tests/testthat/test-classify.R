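test_that("SMOTE balances classes by convex minority interpolation", {
  set.seed(1)
  Xmaj <- matrix(rnorm(120, 5), 60, 2)
  Xmin <- matrix(rnorm(40), 20, 2)
  X <- rbind(Xmaj, Xmin)
  y <- factor(rep(c("HC", "BP"), c(60, 20)), levels = c("HC", "BP"))

  out <- smoteOversample(X, y, smoteConfig(5, seed = 3))
  expect_equal(as.integer(table(out$y)), c(60L, 60L))  # 60/20 -> 60/60
  expect_equal(out$X[seq_len(80), ], X)                # originals preserved
  # synthetic points lie inside the minority bounding box
  synth <- out$X[-seq_len(80), , drop = FALSE]
  expect_true(all(synth[, 1] >= min(Xmin[, 1]) &
                  synth[, 1] <= max(Xmin[, 1])))

  # balanced input is returned unchanged
  yb <- factor(rep(c("HC", "BP"), each = 20))
  Xb <- matrix(rnorm(80), 40, 2)
  ub <- smoteOversample(Xb, yb, smoteConfig(3))
  expect_identical(ub$X, Xb)

  expect_error(smoteOversample(X, y, smoteConfig(20)), "kNeighbors < 20")
})

test_that("with two minority points every synthetic sample is on their segment", {
  a <- c(0, 0); b <- c(2, 4)
  X <- rbind(matrix(rnorm(20, 10), 10, 2), rbind(a, b))
  y <- factor(rep(c("HC", "DP"), c(10, 2)), levels = c("HC", "DP"))
  out <- smoteOversample(X, y, smoteConfig(1, seed = 8))
  synth <- out$X[-seq_len(12), , drop = FALSE]
  expect_equal(nrow(synth), 8)
  # on segment [a, b]: coordinates proportional, parameter within [0, 1]
  u <- synth[, 2] / 4
  expect_equal(synth[, 1], 2 * u, tolerance = 1e-12)
  expect_true(all(u >= 0 & u <= 1))
})

test_that("confusion-matrix metrics match hand-computed values", {
  m <- metricsFromConfusion(matrix(c(60, 0, 0, 20), 2,
                                   dimnames = list(c("HC", "DP"),
                                                   c("HC", "DP"))))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$overallAccuracy, 1)
  expect_equal(unname(m$precision), c(1, 1))

  expect_error(metricsFromConfusion(matrix(c(5, 0, 3, 0), 2)), "at least one")
  expect_error(metricsFromConfusion(matrix(-1:2, 2)), "nonnegative")

  # balanced accuracy is exactly the sensitivity/specificity mean
  set.seed(2)
  for (i in 1:20) {
    cm <- matrix(rpois(4, 20) + 1, 2)
    mm <- metricsFromConfusion(cm)
    expect_equal(mm$balancedAccuracy,
                 (mm$sensitivity + mm$specificity) / 2)
  }
})

test_that("screening separates a wide-margin synthetic cohort perfectly", {
  set.seed(11)
  X <- rbind(matrix(rnorm(60 * 20, 0, 0.1), 60, 20),
             matrix(rnorm(20 * 20, 6, 0.1), 20, 20))
  y <- factor(rep(c("HC", "SZ"), c(60, 20)), levels = c("HC", "SZ"))
  res <- runScreening(X, labels = y, grid = smallGrid(),
                      cv = cvConfig(seed = 5))
  expect_equal(balancedAccuracy(res), 1)
  expect_equal(unname(confusionMatrix(res)), matrix(c(60, 0, 0, 20), 2))
})

test_that("the pooled confusion matrix preserves cohort row sums", {
  fs <- generateFeatureTable(cohortConfig(seed = 2), scheme = "three_scale")
  res <- runScreening(fs, "HC vs DP", grid = smallGrid(),
                      cv = cvConfig(seed = 2))
  expect_equal(unname(rowSums(confusionMatrix(res))), c(60, 20))
  expect_equal(res@comparison, "HC vs DP")
  expect_length(res@bestParams, 5)
  m <- screeningMetrics(res)
  expect_equal(m$balancedAccuracy, (m$sensitivity + m$specificity) / 2)
})

test_that("held-out samples cannot influence model selection (no leakage)", {
  # Perturbing one sample must leave the selected hyperparameters of the
  # folds in which that sample is held out unchanged: fold-level selection
  # sees only training data.
  set.seed(21)
  X <- rbind(matrix(rnorm(40 * 4, 0, 1), 40, 4),
             matrix(rnorm(15 * 4, 1.2, 1), 15, 4))
  y <- factor(rep(c("HC", "BP"), c(40, 15)), levels = c("HC", "BP"))
  cv <- cvConfig(seed = 9)
  resA <- runScreening(X, labels = y, grid = smallGrid(), cv = cv)
  victim <- 7L
  X2 <- X; X2[victim, ] <- X2[victim, ] + 1000
  resB <- runScreening(X2, labels = y, grid = smallGrid(), cv = cv)
  folds <- NSRscreen:::stratifiedFolds(y, 5, 9)
  heldOut <- which(vapply(folds, function(f) victim %in% f, logical(1)))
  expect_length(heldOut, 1)
  expect_identical(resA@bestParams[[heldOut]][c("kernel", "C", "gamma",
                                                "smoteK")],
                   resB@bestParams[[heldOut]][c("kernel", "C", "gamma",
                                                "smoteK")])
})

test_that("3-scale features screen at least as well as direct areas (soft)", {
  # averaged over seeds, quantized features must not trail the raw-area
  # scheme by more than 0.05 balanced accuracy
  d3 <- dd <- numeric(0)
  for (sd in 1:6) {
    f3 <- generateFeatureTable(cohortConfig(seed = sd),
                               scheme = "three_scale")
    fd <- generateFeatureTable(cohortConfig(seed = sd),
                               scheme = "direct_area")
    cmp <- c("HC vs DP", "HC vs BP", "HC vs SZ")[(sd - 1) %% 3 + 1]
    d3 <- c(d3, balancedAccuracy(runScreening(f3, cmp,
                                              cv = cvConfig(seed = sd))))
    dd <- c(dd, balancedAccuracy(runScreening(fd, cmp,
                                              cv = cvConfig(seed = sd))))
  }
  expect_gte(mean(d3), mean(dd) - 0.05)
  # the calibrated moderate effect keeps both schemes in the (0.6, 0.9) band
  expect_gt(mean(d3), 0.6); expect_lt(mean(d3), 0.9)
  expect_gt(mean(dd), 0.6); expect_lt(mean(dd), 0.9)
})

test_that("with no group effect screening hovers at chance", {
  nullKin <- flushKinetics(effectSize = 0)
  bas <- vapply(1:10, function(sd) {
    fs <- generateFeatureTable(cohortConfig(seed = sd), nullKin,
                               scheme = "three_scale")
    balancedAccuracy(runScreening(fs, "HC vs SZ", grid = smallGrid(),
                                  cv = cvConfig(seed = sd)))
  }, numeric(1))
  # pooled-CV balanced accuracy sits slightly below 0.5 under the null
  # (the usual pessimistic bias at n = 80); chance-level band check
  expect_gt(mean(bas), 0.40)
  expect_lt(mean(bas), 0.60)
  expect_true(all(bas >= 0.3 & bas <= 0.7))
})

test_that("score-threshold baselines behave as the classical rules", {
  # all participants score 2 at 0.1 M -> nobody below cutoff 2 -> all HC
  vals <- matrix(2L, 20, 8)
  fs <- NsrFeatureSet(vals, sprintf("p%02d", 1:8),
                      rep(c("HC", "SZ"), 4), "three_scale")
  pred <- baselineScoreClassifier(fs, 0.1, 20, cutoff = 2)
  expect_true(all(pred == "HC"))

  # all-zero score table -> zero total for everyone
  fs0 <- NsrFeatureSet(matrix(0L, 20, 5), sprintf("q%d", 1:5),
                       rep("HC", 5), "three_scale")
  expect_equal(unname(totalScore(fs0)), rep(0, 5))

  expect_error(baselineScoreClassifier(fs, 0.05, 20), "no score")

  # on a cohort with a real effect the baseline beats chance on both axes
  # (0.1 M at 10 min, where the slower patient kinetics are most visible)
  fs2 <- generateFeatureTable(cohortConfig(seed = 6),
                              scheme = "three_scale")
  pred2 <- baselineScoreClassifier(fs2, 0.1, 10, cutoff = 2)
  truth <- factor(ifelse(groupLabels(fs2) == "HC", "HC", "patient"),
                  levels = c("HC", "patient"))
  sens <- mean(pred2[truth == "patient"] == "patient")
  spec <- mean(pred2[truth == "HC"] == "HC")
  expect_gt(sens, 0.5)
  expect_gt(spec, 0.5)
})
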