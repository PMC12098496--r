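# Sliding-window dynamic functional connectivity and k-means brain states.
#
# Windows of length L are slid in steps of s across each subject's series;
# each window yields a Fisher-z correlation matrix, vectorized over the
# strict upper triangle.  Windows are pooled across subjects and clustered
# with Lloyd's k-means (k-means++ seeding, best of n restarts by SSE); the
# number of states is chosen by the maximum-chord-distance elbow on the SSE
# curve, with silhouette and Calinski-Harabasz indices reported alongside.

#' Sliding-window Fisher-z connectivity
#'
#' Window w covers volumes `[(w-1)s + 1, (w-1)s + L]`, giving
#' `W = floor((T - L)/s) + 1` windows.  Pearson correlations per region pair
#' per window are clipped to +/-(1 - 1e-7) and Fisher-z transformed.  A
#' region constant within a window has its correlations in that window set
#' to 0 with a warning.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @param L window length in volumes (>= 3).
#' @param s sliding step in volumes.
#' @return a [WindowedFCStack-class].
#' @export
slidingWindowFC <- function(ts, L = 50L, s = 1L) {
  stopifnot(is(ts, "SubjectTimeSeries"))
  X <- tsData(ts)
  Tn <- nrow(X); P <- ncol(X)
  L <- as.integer(L); s <- as.integer(s)
  if (L < 3L) .stopf("window length must be >= 3")
  if (Tn < L) .stopf("T = %d shorter than window length %d", Tn, L)
  W <- (Tn - L) %/% s + 1L
  starts <- (seq_len(W) - 1L) * s + 1L
  E <- P * (P - 1L) / 2L
  Z <- matrix(0, W, E)
  constSeen <- FALSE
  # rolling raw sums: crossprod and column sums updated per step
  S <- crossprod(X[1:L, , drop = FALSE])
  cs <- colSums(X[1:L, , drop = FALSE])
  for (w in seq_len(W)) {
    if (w > 1L) {  # slide: drop s leading rows, add s trailing rows
      out <- X[(starts[w - 1L]):(starts[w] - 1L), , drop = FALSE]
      inc <- X[(starts[w - 1L] + L):(starts[w] + L - 1L), , drop = FALSE]
      S <- S - crossprod(out) + crossprod(inc)
      cs <- cs - colSums(out) + colSums(inc)
    }
    Cv <- (S - tcrossprod(cs) / L) / (L - 1)       # window covariance
    v <- diag(Cv)
    const <- v < 1e-12 * pmax(1, abs(cs / L))^2
    if (any(const)) {
      constSeen <- TRUE
      v[const] <- 1                                 # avoid 0/0; zero below
    }
    r <- Cv / sqrt(tcrossprod(v))
    if (any(const)) { r[const, ] <- 0; r[, const] <- 0 }
    Z[w, ] <- .fisherZ(.vecUT(r))
  }
  if (constSeen)
    .warnf("subject %s: constant region(s) within some windows; their correlations were set to 0",
           subjectID(ts))
  colnames(Z) <- .edgeNames(regionIDs(ts))
  new("WindowedFCStack", subjectID = subjectID(ts), L = L, s = s,
      zEdges = Z, windowStarts = starts, regionIDs = regionIDs(ts))
}

#' Temporal variability of dynamic connectivity
#'
#' Sample standard deviation (denominator W - 1) of the Fisher-z value of
#' each edge across windows.
#'
#' @param stack a [WindowedFCStack-class] with at least 2 windows.
#' @return named numeric vector, one SD per edge.
#' @export
dfcVariability <- function(stack) {
  stopifnot(is(stack, "WindowedFCStack"))
  Z <- zEdges(stack)
  if (nrow(Z) < 2L) .stopf("need at least 2 windows to compute variability")
  apply(Z, 2, stats::sd)
}

## ---- k-means (Lloyd, k-means++ seeding, matmul distances) ----

.kppInit <- function(X, k, xsq = rowSums(X^2)) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- pmax(xsq - 2 * drop(X %*% X[centers[1], ]) + xsq[centers[1]], 0)
  for (j in seq_len(k - 1L)) {
    centers[j + 1L] <- sample.int(n, 1, prob = d2 / sum(d2))
    cNew <- centers[j + 1L]
    d2 <- pmin(d2, pmax(xsq - 2 * drop(X %*% X[cNew, ]) + xsq[cNew], 0))
  }
  X[centers, , drop = FALSE]
}

# one Lloyd run (compiled, Hamerly bounds); assignments returned 1-based
.lloyd <- function(X, C, maxIter) {
  fit <- .lloydCpp(X, C, as.integer(maxIter))
  fit$assign <- fit$assign + 1L
  fit
}

.kmeansFit <- function(X, k, nInit, maxIter, seed) {
  set.seed(seed)
  xsq <- rowSums(X^2)
  best <- NULL
  for (r in seq_len(nInit)) {
    fit <- .lloyd(X, .kppInit(X, k, xsq), maxIter)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  best
}

.poolStacks <- function(stacks) {
  stopifnot(length(stacks) >= 1, all(vapply(stacks, is, logical(1), "WindowedFCStack")))
  list(X = do.call(rbind, lapply(stacks, zEdges)),
       sizes = vapply(stacks, function(s) nrow(zEdges(s)), integer(1)),
       ids = vapply(stacks, subjectID, character(1)),
       regionIDs = regionIDs(stacks[[1]]))
}

#' Fit the k-state connectivity model
#'
#' Lloyd's k-means on pooled window vectors: k-means++ initialization, best
#' of `nInit` restarts by SSE, centroid update = mean of assigned vectors,
#' convergence when assignments stop changing.  An empty cluster is
#' re-seeded at the point farthest from its centroid.
#'
#' @param stacks list of [WindowedFCStack-class], one per subject.
#' @param k number of states.
#' @param nInit random restarts.
#' @param seed integer seed.
#' @param maxIter iteration cap per restart.
#' @return a [StateModel-class].
#' @export
fitStates <- function(stacks, k, nInit = 20L, seed = 1L, maxIter = 300L) {
  pool <- .poolStacks(stacks)
  if (nrow(pool$X) < k) .stopf("fewer pooled windows (%d) than states (%d)",
                               nrow(pool$X), k)
  fit <- .kmeansFit(pool$X, k, nInit, maxIter, seed)
  labels <- split(fit$assign, rep(seq_along(pool$sizes), pool$sizes))
  names(labels) <- pool$ids
  new("StateModel", k = as.integer(k), centroids = fit$centers,
      labels = labels, SSE = fit$sse,
      selection = data.frame(), regionIDs = pool$regionIDs,
      seed = as.integer(seed))
}

.silhouetteMean <- function(X, assign, sampleCap, seed) {
  if (length(unique(assign)) < 2L) return(NA_real_)
  n <- nrow(X)
  idx <- if (n > sampleCap) {
    set.seed(seed); sort(sample.int(n, sampleCap))
  } else seq_len(n)
  # subsampling can drop a cluster entirely; silhouette needs >= 2
  if (length(unique(assign[idx])) < 2L) return(NA_real_)
  sil <- cluster::silhouette(assign[idx], stats::dist(X[idx, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

.calinskiHarabasz <- function(X, assign, sse) {
  n <- nrow(X); k <- length(unique(assign))
  if (k < 2L) return(NA_real_)
  totss <- sum(sweep(X, 2, colMeans(X))^2)
  between <- totss - sse
  (between / (k - 1)) / (sse / (n - k))
}

# elbow = k maximizing perpendicular distance of the normalized SSE curve to
# the chord joining its endpoints
.elbowK <- function(ks, sse) {
  x <- (ks - ks[1]) / (ks[length(ks)] - ks[1])
  y <- (sse - sse[length(sse)]) / (sse[1] - sse[length(sse)])
  # chord runs (0,1) -> (1,0); distance to line x + y - 1 = 0
  d <- abs(x + y - 1) / sqrt(2)
  interior <- d[-c(1, length(d))]
  if (all(interior < 1e-9)) return(NA_integer_)  # curve is a straight line
  ks[which.max(d)]
}

#' Choose the number of states
#'
#' Fits every k in `kRange`, locates the SSE elbow as the k of maximum
#' perpendicular distance to the chord joining the curve's endpoints, and
#' reports silhouette and Calinski-Harabasz maxima alongside.  The elbow
#' wins on disagreement (a message notes it); if the SSE curve is exactly
#' linear (no elbow) the silhouette argmax is used as fallback.  A
#' non-monotone SSE curve (restart noise) is re-fit once with triple the
#' restarts before the elbow search.
#'
#' @param stacks list of [WindowedFCStack-class].
#' @param kRange candidate state counts (default 2..8).
#' @param nInit k-means restarts per candidate.
#' @param seed integer seed.
#' @param maxIter iteration cap per restart.
#' @param silhouetteSample cap on windows entering the silhouette
#'   computation (it needs an O(n^2) distance matrix); sampled with the
#'   fit's seed when exceeded.
#' @return the fitted [StateModel-class] at the chosen k; its
#'   `selectionTable()` has one row per candidate (`k`, `SSE`, `silhouette`,
#'   `CH`) plus attributes `chosenK`, `elbowK`, `silhouetteK`, `chK`.
#' @export
selectK <- function(stacks, kRange = 2:8, nInit = 20L, seed = 1L,
                    maxIter = 300L, silhouetteSample = 1000L) {
  pool <- .poolStacks(stacks)
  if (max(kRange) > nrow(pool$X))
    .stopf("kRange exceeds the pooled window count")
  fitOne <- function(k, nI)
    .kmeansFit(pool$X, k, nI, maxIter, .deriveSeed(seed, k))
  fits <- lapply(kRange, fitOne, nI = nInit)
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  if (any(diff(sse) > 0)) {  # restart noise: refit offenders harder
    for (i in which(c(FALSE, diff(sse) > 0)))
      fits[[i]] <- fitOne(kRange[i], 3L * nInit)
    sse <- vapply(fits, `[[`, numeric(1), "sse")
  }
  sil <- vapply(seq_along(kRange), function(i)
    .silhouetteMean(pool$X, fits[[i]]$assign, silhouetteSample,
                    .deriveSeed(seed, 1000L + kRange[i])), numeric(1))
  ch <- vapply(seq_along(kRange), function(i)
    .calinskiHarabasz(pool$X, fits[[i]]$assign, sse[i]), numeric(1))
  tab <- data.frame(k = kRange, SSE = sse, silhouette = sil, CH = ch)
  elbow <- .elbowK(kRange, sse)
  silK <- kRange[which.max(sil)]
  chK <- kRange[which.max(ch)]
  chosen <- if (is.na(elbow)) {
    message("SSE curve has no elbow; falling back to the silhouette argmax")
    silK
  } else elbow
  if (!is.na(elbow) && (silK != chosen || chK != chosen))
    message(sprintf(
      "model-selection indices disagree (elbow %d, silhouette %d, CH %d); keeping the elbow",
      elbow, silK, chK))
  i <- match(chosen, kRange)
  labels <- split(fits[[i]]$assign, rep(seq_along(pool$sizes), pool$sizes))
  names(labels) <- pool$ids
  attr(tab, "chosenK") <- chosen
  attr(tab, "elbowK") <- elbow
  attr(tab, "silhouetteK") <- silK
  attr(tab, "chK") <- chK
  new("StateModel", k = as.integer(chosen), centroids = fits[[i]]$centers,
      labels = labels, SSE = sse[i], selection = tab,
      regionIDs = pool$regionIDs, seed = as.integer(seed))
}

## ---- state dynamics ----

.runLengths <- function(lab) {
  r <- rle(lab)
  data.frame(state = r$values, length = r$lengths)
}

#' Per-subject state dynamics
#'
#' Fractional occupancy, mean dwell time (mean length of maximal runs, in
#' windows), number of transitions, and transition frequency
#' (transitions / (W - 1)).  The dwell time of an unvisited state is NA.
#'
#' @param model a [StateModel-class].
#' @return data.frame, one row per subject: `subject`, `transitions`,
#'   `transition_frequency`, `occupancy_<j>` and `dwell_<j>` for each state.
#' @export
stateDynamics <- function(model) {
  stopifnot(is(model, "StateModel"))
  k <- model@k
  rows <- lapply(names(stateLabels(model)), function(id) {
    lab <- stateLabels(model)[[id]]
    W <- length(lab)
    if (W < 2L) .stopf("subject %s has a single window; transitions undefined", id)
    runs <- .runLengths(lab)
    occ <- tabulate(lab, nbins = k) / W
    dwell <- vapply(seq_len(k), function(j) {
      lj <- runs$length[runs$state == j]
      if (length(lj)) mean(lj) else NA_real_
    }, numeric(1))
    trans <- nrow(runs) - 1L
    out <- data.frame(subject = id, transitions = trans,
                      transition_frequency = trans / (W - 1L))
    out[paste0("occupancy_", seq_len(k))] <- as.list(occ)
    out[paste0("dwell_", seq_len(k))] <- as.list(dwell)
    out
  })
  do.call(rbind, rows)
}

#' State-wise mean connectivity per subject
#'
#' For each subject and state, the mean of that subject's window Fisher-z
#' vectors assigned to the state; a state the subject never visits is NA.
#'
#' @param model a [StateModel-class].
#' @param stacks the stacks the model was fitted on (same order as fitting).
#' @return numeric array subjects x states x edges with dimnames.
#' @export
statewiseConnectivity <- function(model, stacks) {
  stopifnot(is(model, "StateModel"))
  ids <- vapply(stacks, subjectID, character(1))
  if (!identical(ids, names(stateLabels(model))))
    .stopf("stacks do not match the model's subjects")
  k <- model@k
  E <- ncol(centroids(model))
  out <- array(NA_real_, dim = c(length(ids), k, E),
               dimnames = list(ids, paste0("state", seq_len(k)),
                               colnames(zEdges(stacks[[1]]))))
  for (i in seq_along(stacks)) {
    Z <- zEdges(stacks[[i]])
    lab <- stateLabels(model)[[i]]
    for (j in seq_len(k)) {
      w <- lab == j
      if (any(w)) out[i, j, ] <- colMeans(Z[w, , drop = FALSE])
    }
  }
  out
}
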