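# Feature assembly, confusion metrics, cross-validation, feature ranking.

sepData <- function(n = 40, gap = 5, p = 6, seed = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
  y <- rep(c("patient", "control"), each = n / 2)
  x[, p] <- x[, p] + ifelse(y == "patient", gap / 2, -gap / 2)
  list(x = x, y = y)
}

test_that("confusion metrics reproduce the worked example to 3 d.p.", {
  m <- confusionMetrics(TP = 27, FP = 2, TN = 32, FN = 5)
  expect_equal(round(m[["accuracy"]], 3), 0.894)
  expect_equal(round(m[["sensitivity"]], 3), 0.844)
  expect_equal(round(m[["specificity"]], 3), 0.941)
  expect_equal(m[["precision"]], 27 / 29)
})

test_that("confusion metrics handle symmetric, perfect and degenerate counts", {
  m <- confusionMetrics(TP = 10, FN = 10, TN = 7, FP = 7)
  expect_equal(m[["sensitivity"]], 0.5)
  expect_equal(m[["specificity"]], 0.5)
  mp <- confusionMetrics(TP = 12, FP = 0, TN = 9, FN = 0)
  expect_true(all(mp == 1))
  expect_warning(mz <- confusionMetrics(TP = 0, FP = 0, TN = 5, FN = 5),
                 "precision undefined")
  expect_true(is.na(mz[["precision"]]))
  expect_error(confusionMetrics(TP = 0, FP = 0, TN = 0, FN = 0), "zero")
  # named-vector form
  expect_equal(confusionMetrics(c(TP = 27, FP = 2, TN = 32, FN = 5)),
               confusionMetrics(27, 2, 32, 5))
})

test_that("LOOCV produces one fold per subject; 5-fold is stratified", {
  d <- sepData(n = 20)
  cv <- crossValidate(d$x, d$y, "svm-linear", "loocv", seed = 1)
  expect_equal(length(unique(cvPredictions(cv)$fold)), 20)
  expect_true(all(table(cvPredictions(cv)$fold) == 1))
  cv5 <- crossValidate(d$x, d$y, "svm-linear", "5fold", seed = 1)
  byFold <- table(cvPredictions(cv5)$fold, cvPredictions(cv5)$truth)
  expect_true(all(byFold == 2))  # 10 per class over 5 folds
})

test_that("a wide class gap is perfectly separated by the linear margin", {
  d <- sepData(n = 30, gap = 5)
  cv <- crossValidate(d$x, d$y, "svm-linear", "loocv", seed = 1)
  expect_equal(cvMetrics(cv)[["auc"]], 1)
  expect_equal(sum(confusionCounts(cv)), 30)
})

test_that("every classifier runs and beats chance on separable data", {
  d <- sepData(n = 30, gap = 4, seed = 5)
  for (cl in c("svm-linear", "svm-rbf", "knn", "rf", "xgboost")) {
    cv <- crossValidate(d$x, d$y, cl, "5fold", seed = 3)
    expect_gte(cvMetrics(cv)[["auc"]], 0.9)
    expect_s4_class(cv, "CVResult")
  }
})

test_that("pooled AUC equals the Mann-Whitney rank statistic", {
  set.seed(6)
  for (i in 1:30) {
    n <- 30
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    score <- round(rnorm(n, mean = truth), 1)  # rounding forces ties
    rc <- gradstates:::.rocCurve(score, truth)
    expect_equal(rc$auc, rankAUC(score, truth), tolerance = 1e-10)
  }
})

test_that("stored metrics are reproducible from stored predictions", {
  d <- sepData(n = 24, gap = 2, seed = 7)
  cv <- crossValidate(d$x, d$y, "knn", "loocv", seed = 2)
  pr <- cvPredictions(cv)
  cc <- confusionCounts(cv)
  n <- nrow(pr)
  expect_equal(cc[["TP"]], sum(pr$predicted == "patient" & pr$truth == "patient"))
  # accuracy identity from sensitivity/specificity
  m <- cvMetrics(cv)
  expect_equal(m[["accuracy"]],
               (m[["sensitivity"]] * (cc[["TP"]] + cc[["FN"]]) +
                m[["specificity"]] * (cc[["TN"]] + cc[["FP"]])) / n)
  expect_equal(m[["auc"]], gradstates:::.rocCurve(pr$score,
               as.numeric(pr$truth == "patient"))$auc)
})

test_that("standardization parameters come from training folds only", {
  d <- sepData(n = 26, gap = 1, seed = 8)
  cv <- crossValidate(d$x, d$y, "svm-linear", "5fold", seed = 4)
  sc <- cv@scaling
  pr <- cvPredictions(cv)
  for (f in unique(sc$fold)) {
    tr <- which(pr$fold != f)
    expect_equal(sc$center[sc$fold == f],
                 unname(colMeans(d$x[tr, , drop = FALSE])), tolerance = 1e-12)
    expect_equal(sc$scale[sc$fold == f],
                 unname(apply(d$x[tr, , drop = FALSE], 2, sd)),
                 tolerance = 1e-12)
  }
})

test_that("feature assembly yields the 24-column table and guards integrity", {
  set.seed(9)
  n <- 20
  gv <- matrix(rnorm(n * 60), n, 60)
  ct <- data.frame(cluster = 1:12, region = rep(c("a", "b"), 6),
                   start = seq(1, 56, by = 5), end = seq(3, 58, by = 5),
                   size = 3, peak_t = rnorm(12, 4), cluster_p = 0.01,
                   significant = TRUE)
  dv <- matrix(rnorm(n * 30), n, 30,
               dimnames = list(NULL, paste0("e", 1:30)))
  ds <- data.frame(feature = paste0("e", 1:30), t = rnorm(30), p = 0.01,
                   direction = 1L, df = 16, significant = rep(c(TRUE, FALSE),
                                                              c(15, 15)))
  ft <- assembleFeatures(gv, ct, dv, ds, topN = 12)
  expect_equal(ncol(ft$x), 24)
  expect_equal(sum(startsWith(colnames(ft$x), "FG:")), 12)
  expect_equal(sum(startsWith(colnames(ft$x), "dFC:")), 12)
  expect_equal(nrow(ft$provenance), 24)
  # fewer candidates than requested: all used, message emitted
  expect_message(ft2 <- assembleFeatures(gv, ct[1:3, ], dv, ds, topN = 12),
                 "candidate")
  expect_equal(sum(startsWith(colnames(ft2$x), "FG:")), 3)
  # no candidates at all
  expect_error(assembleFeatures(gv, ct[0, ], dv, ds[0, ], topN = 0),
               "no features")
  # a missing value is named
  dv[3, 1] <- NA
  expect_error(assembleFeatures(gv, ct, dv, ds, topN = 12), "missing value")
})

test_that("recursive elimination ranks a planted feature first", {
  top1 <- vapply(1:20, function(sd) {
    d <- sepData(n = 30, gap = 3, p = 8, seed = 100 + sd)
    rk <- rankFeatures(d$x, d$y)
    rk$feature[1] == "f8"
  }, logical(1))
  expect_gte(sum(top1), 18)
})

test_that("duplicated feature columns occupy adjacent ranks", {
  d <- sepData(n = 30, gap = 2, p = 5, seed = 11)
  x2 <- cbind(d$x, f5copy = d$x[, 5])
  rk <- suppressMessages(rankFeatures(x2, d$y))
  r5 <- which(rk$feature == "f5")
  rcopy <- which(rk$feature == "f5copy")
  expect_equal(abs(r5 - rcopy), 1)
})

test_that("all-noise features yield no stable top feature", {
  tops <- vapply(1:12, function(sd) {
    set.seed(400 + sd)
    x <- matrix(rnorm(30 * 6), 30, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- rep(c("patient", "control"), each = 15)
    rankFeatures(x, y)$feature[1]
  }, character(1))
  expect_gt(length(unique(tops)), 2)
})

test_that("weight-magnitude ranking is available and consistent", {
  d <- sepData(n = 30, gap = 4, seed = 12)
  rk <- rankFeatures(d$x, d$y, method = "weight")
  expect_equal(rk$feature[1], "f6")
  expect_equal(nrow(rk), 6)
})
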