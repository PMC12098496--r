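# Feature assembly, confusion-matrix metrics, cross-validated evaluation of
# five classifiers, and recursive feature elimination.
#
# Positive class is "patient" throughout.  Features are standardized inside
# training folds only; decision scores are pooled across folds for a single
# ROC/AUC (per-fold ROCs are undefined at LOOCV test size 1).

#' Assemble the classification feature table
#'
#' Combines (1) mean aligned gradient scores within selected voxel clusters
#' and (2) dynamic-connectivity values at selected edges.  Clusters/edges
#' marked significant are used first (ordered by |t|); when none are
#' significant the top `topN` by |t| are used instead, and when fewer
#' candidates exist than `topN` all are used (both reported).  The default
#' `topN = 12` per source yields the conventional 24-feature table.
#'
#' @param gradientValues numeric subjects x voxels matrix of aligned,
#'   z-scored gradient scores.
#' @param clusterTable output of [clusterCorrectPermutation()] on those
#'   voxels.
#' @param dfcValues numeric subjects x edges matrix (variability map or
#'   state-wise connectivity).
#' @param dfcStats output of [adjustedGroupTest()] on `dfcValues`, with a
#'   logical `significant` column (e.g. from [fdrCorrect()]).
#' @param topN features drawn from each source.
#' @return list with `x` (subjects x features matrix, names
#'   `FG:<region>:<start>-<end>` / `dFC:<edge>`) and `provenance`
#'   (data.frame `feature`, `source`, `selected_by`, `t`).
#' @export
assembleFeatures <- function(gradientValues, clusterTable, dfcValues,
                             dfcStats, topN = 12L) {
  gradientValues <- as.matrix(gradientValues)
  dfcValues <- as.matrix(dfcValues)
  if (nrow(gradientValues) != nrow(dfcValues))
    .stopf("gradient and dFC tables must describe the same subjects")
  pick <- function(cand, sig, ord, n) {
    idx <- if (any(sig)) which(sig)[order(-ord[sig])] else order(-ord)
    mode <- if (any(sig)) "significant" else "top-|t|"
    if (length(idx) < n)
      message(sprintf("only %d candidate(s) available (requested %d)",
                      length(idx), n))
    list(idx = idx[seq_len(min(n, length(idx)))], mode = mode)
  }
  cols <- list(); prov <- list()
  if (nrow(clusterTable)) {
    sel <- pick(seq_len(nrow(clusterTable)), clusterTable$significant,
                abs(clusterTable$peak_t), topN)
    for (ci in sel$idx) {
      vox <- clusterTable$start[ci]:clusterTable$end[ci]
      nm <- sprintf("FG:%s:%d-%d", clusterTable$region[ci],
                    clusterTable$start[ci], clusterTable$end[ci])
      cols[[nm]] <- rowMeans(gradientValues[, vox, drop = FALSE])
      prov[[nm]] <- data.frame(feature = nm, source = "FG",
                               selected_by = sel$mode,
                               t = clusterTable$peak_t[ci])
    }
  }
  sig <- if ("significant" %in% names(dfcStats)) dfcStats$significant else
    rep(FALSE, nrow(dfcStats))
  sel <- pick(seq_len(nrow(dfcStats)), sig, abs(dfcStats$t), topN)
  for (ei in sel$idx) {
    nm <- paste0("dFC:", dfcStats$feature[ei])
    cols[[nm]] <- dfcValues[, as.character(dfcStats$feature[ei])]
    prov[[nm]] <- data.frame(feature = nm, source = "dFC",
                             selected_by = sel$mode, t = dfcStats$t[ei])
  }
  if (!length(cols)) .stopf("no features selected (no candidates and topN = 0?)")
  x <- do.call(cbind, cols)
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    .stopf("missing value for subject %s, feature %s",
           rownames(x)[bad[1]] %||% bad[1], colnames(x)[bad[2]])
  }
  list(x = x, provenance = do.call(rbind, c(prov, list(make.row.names = FALSE))))
}

#' Confusion-matrix metrics
#'
#' accuracy = (TP+TN)/(TP+FP+TN+FN); precision = TP/(TP+FP);
#' sensitivity = TP/(TP+FN); specificity = TN/(TN+FP).  A metric with a
#' zero denominator is NA (flagged with a warning).
#'
#' @param TP,FP,TN,FN non-negative integer counts; alternatively pass a
#'   named vector as `TP`.
#' @return named numeric: accuracy, precision, sensitivity, specificity.
#' @export
confusionMetrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.null(FP) && !is.null(names(TP))) {
    cc <- TP; TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
  }
  cc <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(cc < 0) || any(cc != round(cc))) .stopf("counts must be non-negative integers")
  if (sum(cc) == 0) .stopf("all confusion counts are zero")
  safe <- function(num, den, nm) {
    if (den == 0) { .warnf("%s undefined (zero denominator)", nm); NA_real_ }
    else num / den
  }
  c(accuracy = (TP + TN) / sum(cc),
    precision = safe(TP, TP + FP, "precision"),
    sensitivity = safe(TP, TP + FN, "sensitivity"),
    specificity = safe(TN, TN + FP, "specificity"))
}

# ROC points and trapezoidal AUC from pooled decision scores
.rocCurve <- function(score, truth01) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- truth01[ord]
  # collapse tied scores into single operating points
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  P <- sum(truth01); N <- sum(1 - truth01)
  roc <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P),
                    threshold = c(Inf, thr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

.makeFolds <- function(y, scheme, seed) {
  n <- length(y)
  if (scheme == "loocv") return(as.list(seq_len(n)))
  set.seed(seed)
  folds <- vector("list", 5L)
  for (cl in unique(y)) {         # stratified 5-fold
    idx <- sample(which(y == cl))
    grp <- rep(seq_len(5L), length.out = length(idx))
    for (f in seq_len(5L)) folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  folds
}

.fitPredict <- function(classifier, xtr, ytr, xte, seed) {
  yf <- factor(ytr, levels = c("control", "patient"))
  set.seed(seed)
  switch(classifier,
    "svm-linear" = ,
    "svm-rbf" = {
      kern <- if (classifier == "svm-linear") "linear" else "radial"
      m <- e1071::svm(xtr, yf, kernel = kern, cost = 1, scale = FALSE)
      dv <- attr(stats::predict(m, xte, decision.values = TRUE),
                 "decision.values")
      score <- as.numeric(dv[, 1])
      # decision value is positive for the first level named in the colname
      if (!startsWith(colnames(dv)[1], "patient")) score <- -score
      list(score = score, pred = ifelse(score >= 0, "patient", "control"))
    },
    "knn" = {
      pr <- class::knn(xtr, xte, yf, k = 5, prob = TRUE)
      frac <- attr(pr, "prob")
      score <- ifelse(pr == "patient", frac, 1 - frac)
      list(score = score, pred = ifelse(score >= 0.5, "patient", "control"))
    },
    "rf" = {
      m <- randomForest::randomForest(xtr, yf, ntree = 100)
      score <- stats::predict(m, xte, type = "prob")[, "patient"]
      list(score = score, pred = ifelse(score >= 0.5, "patient", "control"))
    },
    "xgboost" = {
      dtr <- xgboost::xgb.DMatrix(xtr, label = as.numeric(yf == "patient"),
                                  nthread = 1)
      m <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                            max_depth = 3, eta = 0.1,
                                            nthread = 1),
                              data = dtr, nrounds = 100)
      score <- stats::predict(m, xgboost::xgb.DMatrix(xte, nthread = 1))
      list(score = score, pred = ifelse(score >= 0.5, "patient", "control"))
    },
    .stopf("unknown classifier '%s'", classifier))
}

#' Cross-validated classifier evaluation
#'
#' Evaluates one of five classifiers - linear-margin SVM (`"svm-linear"`),
#' RBF-kernel SVM (`"svm-rbf"`), k-nearest neighbors (`"knn"`, k = 5),
#' random forest (`"rf"`, 100 trees), gradient-boosted trees (`"xgboost"`,
#' depth 3, 100 rounds) - under leave-one-out or stratified 5-fold CV.
#' Standardization parameters are estimated on each training fold only and
#' recorded; decision scores are pooled across folds into one ROC/AUC.
#'
#' @param x numeric subjects x features matrix.
#' @param y group labels ("patient"/"control").
#' @param classifier one of `"svm-linear"`, `"svm-rbf"`, `"knn"`, `"rf"`,
#'   `"xgboost"`.
#' @param scheme `"loocv"` or `"5fold"`.
#' @param seed integer seed (folding and any stochastic fit).
#' @return a [CVResult-class].
#' @export
crossValidate <- function(x, y,
                          classifier = c("svm-linear", "svm-rbf", "knn",
                                         "rf", "xgboost"),
                          scheme = c("loocv", "5fold"), seed = 1L) {
  classifier <- match.arg(classifier)
  scheme <- match.arg(scheme)
  x <- as.matrix(x); y <- as.character(y)
  n <- nrow(x)
  if (n < 10) .stopf("need at least 10 subjects")
  folds <- .makeFolds(y, scheme, seed)
  pred <- character(n); score <- numeric(n); foldOf <- integer(n)
  scaling <- list()
  for (f in seq_along(folds)) {
    te <- folds[[f]]; tr <- setdiff(seq_len(n), te)
    if (length(unique(y[tr])) < 2)
      .stopf("training fold %d lacks a class; refold with a different seed", f)
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, ctr), 2, scl, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, ctr), 2, scl, "/")
    fit <- .fitPredict(classifier, xtr, y[tr], xte,
                       seed = .deriveSeed(seed, f))
    pred[te] <- fit$pred; score[te] <- fit$score; foldOf[te] <- f
    scaling[[f]] <- data.frame(fold = f,
                               feature = colnames(x) %||% seq_len(ncol(x)),
                               center = unname(ctr), scale = unname(scl))
  }
  truth01 <- as.numeric(y == "patient")
  rc <- .rocCurve(score, truth01)
  counts <- c(TP = sum(pred == "patient" & y == "patient"),
              FP = sum(pred == "patient" & y == "control"),
              TN = sum(pred == "control" & y == "control"),
              FN = sum(pred == "control" & y == "patient"))
  metrics <- c(confusionMetrics(counts), auc = rc$auc)
  new("CVResult", classifier = classifier, scheme = scheme,
      predictions = data.frame(
        subject = rownames(x) %||% seq_len(n), fold = foldOf,
        truth = y, predicted = pred, score = score, row.names = NULL),
      counts = as.integer(counts) |> stats::setNames(names(counts)),
      metrics = metrics, roc = rc$roc,
      scaling = do.call(rbind, scaling), seed = as.integer(seed))
}

# linear SVM feature weights w = t(coefs) %*% SV on standardized inputs
.svmWeights <- function(x, y) {
  yf <- factor(y, levels = c("control", "patient"))
  m <- e1071::svm(x, yf, kernel = "linear", cost = 1, scale = FALSE)
  as.numeric(crossprod(m$coefs, m$SV))
}

#' Rank features by recursive elimination (or weight magnitude)
#'
#' `"rfe"`: repeatedly fits the linear-margin SVM on standardized data and
#' drops the feature with the smallest |weight|, refitting each round; the
#' elimination order (last dropped = rank 1) is the ranking.
#' `"weight"`: single fit, ranked by |weight|.  Exactly tied weights (e.g.
#' duplicated columns) are broken by column order and reported.
#'
#' @param x numeric subjects x features matrix.
#' @param y group labels.
#' @param method `"rfe"` or `"weight"`.
#' @return data.frame `rank`, `feature`, `weight` (weight at elimination
#'   time for RFE).
#' @export
rankFeatures <- function(x, y, method = c("rfe", "weight")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  feats <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  if (method == "weight") {
    w <- .svmWeights(xs, y)
    ord <- order(-abs(w))
    return(data.frame(rank = seq_along(ord), feature = feats[ord],
                      weight = w[ord]))
  }
  remaining <- seq_len(ncol(x))
  dropped <- integer(0); wAtDrop <- numeric(0)
  while (length(remaining) > 1) {
    w <- .svmWeights(xs[, remaining, drop = FALSE], y)
    if (anyDuplicated(abs(w)))
      message("tied |weights|; ties broken by column order")
    worst <- which.min(abs(w))   # first minimum: lower column index wins ties
    dropped <- c(dropped, remaining[worst])
    wAtDrop <- c(wAtDrop, w[worst])
    remaining <- remaining[-worst]
  }
  orderOut <- c(remaining, rev(dropped))
  wOut <- c(NA_real_, rev(wAtDrop))
  data.frame(rank = seq_along(orderOut), feature = feats[orderOut],
             weight = wOut)
}
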