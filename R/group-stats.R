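# Covariate-adjusted mass-univariate group comparisons, multiple-comparison
# control, and clinical correlations.

# t statistic of the group coefficient in value ~ 1 + group + covariates,
# computed for every feature column at once via one QR decomposition
.massUniT <- function(values, group01, covariates = NULL) {
  X <- cbind(1, group01)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) .stopf("design matrix is rank deficient (collinear covariates?)")
  coefs <- qr.coef(qrX, values)
  res <- values - X %*% coefs
  df <- n - p
  sigma2 <- colSums(res^2) / df
  XtXinv22 <- chol2inv(qr.R(qrX))[2, 2]
  tstat <- coefs[2, ] / sqrt(sigma2 * XtXinv22)
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

.group01 <- function(group) {
  if (is.numeric(group)) {
    u <- sort(unique(group))
    if (length(u) != 2) .stopf("group must have exactly 2 levels")
    return(as.numeric(group == u[2]))
  }
  u <- unique(as.character(group))
  if (length(u) != 2) .stopf("group must have exactly 2 levels")
  # patient coded 1 when present, else second level
  pos <- if ("patient" %in% u) "patient" else u[2]
  as.numeric(group == pos)
}

#' Covariate-adjusted mass-univariate group test
#'
#' Per feature, fits `value ~ intercept + group + covariates` and reports
#' the group coefficient's t statistic (df = n - 2 - ncol(covariates)) with
#' its two-sided p.  Group is coded 0/1 with `"patient"` as 1, so positive t
#' means patients > controls.  Without covariates this equals the classical
#' pooled two-sample t test.
#'
#' @param values numeric n x F matrix (subjects x features).
#' @param group group labels of length n (2 levels).
#' @param covariates optional numeric matrix/data.frame of length-n columns
#'   (e.g. age in years, sex coded 0/1).
#' @return data.frame: `feature`, `t`, `p`, `direction` (+1/-1), `df`.
#' @export
adjustedGroupTest <- function(values, group, covariates = NULL) {
  values <- as.matrix(values)
  g <- .group01(group)
  if (min(table(g)) < 3) .stopf("need at least 3 subjects per group")
  fit <- .massUniT(values, g, covariates)
  data.frame(feature = colnames(values) %||% seq_len(ncol(values)),
             t = unname(fit$t), p = unname(fit$p),
             direction = ifelse(fit$t >= 0, 1L, -1L),
             df = fit$df, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q`; returns the significance mask with the
#' adjusted p values as attribute `p_fdr`.
#'
#' @param p p values in (0, 1].
#' @param q FDR level.
#' @return logical vector; attribute `p_fdr` holds BH-adjusted p values.
#' @export
fdrCorrect <- function(p, q = 0.05) {
  if (!length(p)) .stopf("empty p-value vector")
  if (any(p <= 0 | p > 1)) .stopf("p values must lie in (0, 1]")
  padj <- stats::p.adjust(p, method = "BH")
  structure(padj <= q, p_fdr = padj)
}

# maximal runs of supra-threshold voxels, adjacent = consecutive indices
# within the same region
.findClusters <- function(supra, region) {
  n <- length(supra)
  clusters <- list()
  i <- 1L
  while (i <= n) {
    if (supra[i]) {
      j <- i
      while (j < n && supra[j + 1L] && region[j + 1L] == region[i]) j <- j + 1L
      clusters[[length(clusters) + 1L]] <- i:j
      i <- j + 1L
    } else i <- i + 1L
  }
  clusters
}

.maxClusterSize <- function(supra, region) {
  cl <- .findClusters(supra, region)
  if (!length(cl)) 0L else max(lengths(cl))
}

#' Permutation-based cluster-extent correction
#'
#' Forms supra-threshold clusters of the covariate-adjusted group-t map at
#' `voxelP` (two-sided) over a chain adjacency within each region, builds
#' the null distribution of the maximal cluster size from group-label
#' permutations, and assigns each observed cluster
#' `p = (1 + #{null maxima >= size}) / (nPerm + 1)`.
#'
#' @param values numeric n x V matrix (subjects x voxels, voxels ordered so
#'   that consecutive voxels within a region are spatial neighbors).
#' @param group group labels (2 levels, `"patient"` = positive direction).
#' @param regionLabels region label per voxel (adjacency does not cross
#'   regions).
#' @param covariates optional covariate matrix.
#' @param voxelP voxel-forming threshold (two-sided p).
#' @param clusterP cluster-level significance threshold.
#' @param nPerm number of permutations (>= 1/clusterP).
#' @param seed integer seed.
#' @return data.frame, one row per observed cluster: `cluster`, `region`,
#'   `start`, `end`, `size`, `peak_t`, `cluster_p`, `significant`; zero rows
#'   when nothing survives the voxel threshold.
#' @export
clusterCorrectPermutation <- function(values, group, regionLabels,
                                      covariates = NULL, voxelP = 0.001,
                                      clusterP = 0.05, nPerm = 1000L,
                                      seed = 1L) {
  if (nPerm < 1 / clusterP)
    .stopf("nPerm = %d cannot resolve cluster p < %g; need at least %d permutations",
           nPerm, clusterP, ceiling(1 / clusterP))
  values <- as.matrix(values)
  if (length(regionLabels) != ncol(values))
    .stopf("one region label per voxel required")
  g <- .group01(group)
  obs <- .massUniT(values, g, covariates)
  tcrit <- stats::qt(1 - voxelP / 2, obs$df)
  supra <- abs(obs$t) > tcrit
  clusters <- .findClusters(supra, regionLabels)
  empty <- data.frame(cluster = integer(0), region = character(0),
                      start = integer(0), end = integer(0), size = integer(0),
                      peak_t = numeric(0), cluster_p = numeric(0),
                      significant = logical(0))
  if (!length(clusters)) return(empty)
  set.seed(seed)
  nullMax <- integer(nPerm)
  for (b in seq_len(nPerm)) {
    tp <- .massUniT(values, sample(g), covariates)$t
    nullMax[b] <- .maxClusterSize(abs(tp) > tcrit, regionLabels)
  }
  sizes <- lengths(clusters)
  pcl <- vapply(sizes, function(sz) (1 + sum(nullMax >= sz)) / (nPerm + 1),
                numeric(1))
  data.frame(
    cluster = seq_along(clusters),
    region = vapply(clusters, function(ix) regionLabels[ix[1]], regionLabels[1]),
    start = vapply(clusters, min, integer(1)),
    end = vapply(clusters, max, integer(1)),
    size = as.integer(sizes),
    peak_t = vapply(clusters, function(ix) obs$t[ix][which.max(abs(obs$t[ix]))],
                    numeric(1)),
    cluster_p = pcl,
    significant = pcl < clusterP,
    row.names = NULL)
}

#' Pearson correlations between features and clinical variables
#'
#' For every (feature, variable) pair: Pearson r, R-squared = r^2, and the
#' two-sided p from the t transform with n - 2 df, over complete pairs.
#' Pairs with zero variance or fewer than `minN` complete observations are
#' flagged and excluded (NA statistics, `excluded = TRUE`).
#'
#' @param featureScores numeric matrix/data.frame (subjects x features).
#' @param clinical numeric matrix/data.frame (subjects x variables), same
#'   row order.
#' @param minN minimum complete pairs (default 4).
#' @return data.frame: `feature`, `variable`, `r`, `R2`, `p`, `n`,
#'   `excluded`.
#' @export
clinicalCorrelations <- function(featureScores, clinical, minN = 4L) {
  featureScores <- as.matrix(featureScores)
  clinical <- as.matrix(clinical)
  if (nrow(featureScores) != nrow(clinical))
    .stopf("featureScores and clinical must describe the same subjects")
  fnames <- colnames(featureScores) %||% paste0("feature", seq_len(ncol(featureScores)))
  vnames <- colnames(clinical) %||% paste0("var", seq_len(ncol(clinical)))
  out <- expand.grid(feature = fnames, variable = vnames,
                     stringsAsFactors = FALSE)
  stats_ <- t(mapply(function(f, v) {
    x <- featureScores[, f]; y <- clinical[, v]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < minN || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(NA_real_, NA_real_, NA_real_, n, 1))
    r <- stats::cor(x[ok], y[ok])
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r, r^2, 2 * stats::pt(-abs(tt), n - 2), n, 0)
  }, out$feature, out$variable))
  out$r <- stats_[, 1]; out$R2 <- stats_[, 2]; out$p <- stats_[, 3]
  out$n <- as.integer(stats_[, 4]); out$excluded <- stats_[, 5] == 1
  out
}
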