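#' @import methods
NULL

#' SubjectTimeSeries: one subject's region-by-time BOLD matrix
#'
#' The pipeline's atomic input: a T x P matrix of band-limited BOLD signal
#' (rows = time points sampled every `TR` seconds, columns = regions), plus
#' the subject's identifier and group label.
#'
#' @slot subjectID single character identifier.
#' @slot group group label, `"patient"` or `"control"`.
#' @slot data numeric T x P matrix, rows = time, columns = regions.
#' @slot TR repetition time in seconds (sampling interval).
#' @slot regionIDs character vector of region identifiers, aligned with the
#'   columns of `data`.
#'
#' @exportClass SubjectTimeSeries
setClass("SubjectTimeSeries",
  representation(
    subjectID = "character",
    group     = "character",
    data      = "matrix",
    TR        = "numeric",
    regionIDs = "character"
  )
)

setValidity("SubjectTimeSeries", function(object) {
  msg <- character()
  if (length(object@subjectID) != 1L) msg <- c(msg, "subjectID must be length 1")
  if (length(object@group) != 1L || !object@group %in% c("patient", "control"))
    msg <- c(msg, "group must be 'patient' or 'control'")
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "data must be numeric")
  if (anyNA(d) || any(!is.finite(d))) msg <- c(msg, "data contains missing or non-finite values")
  if (nrow(d) < 2L) msg <- c(msg, "need at least 2 time points")
  if (ncol(d) < 2L) msg <- c(msg, "need at least 2 regions")
  if (length(object@TR) != 1L || object@TR <= 0) msg <- c(msg, "TR must be a positive scalar")
  if (length(object@regionIDs) != ncol(d)) msg <- c(msg, "regionIDs must match the number of columns")
  if (anyDuplicated(object@regionIDs)) msg <- c(msg, "regionIDs must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a SubjectTimeSeries
#'
#' @param subjectID subject identifier.
#' @param group `"patient"` or `"control"`.
#' @param data numeric T x P matrix (rows = time, columns = regions).
#' @param TR repetition time in seconds.
#' @param regionIDs region identifiers; defaults to the column names of
#'   `data`, or `"R001"`-style labels when those are absent.
#' @return A [SubjectTimeSeries-class] object.
#' @export
SubjectTimeSeries <- function(subjectID, group, data, TR = 2,
                              regionIDs = colnames(data)) {
  data <- as.matrix(data)
  if (is.null(regionIDs))
    regionIDs <- sprintf("R%03d", seq_len(ncol(data)))
  colnames(data) <- regionIDs
  new("SubjectTimeSeries", subjectID = as.character(subjectID),
      group = as.character(group), data = data, TR = as.numeric(TR),
      regionIDs = as.character(regionIDs))
}

#' WindowedFCStack: sliding-window Fisher-z connectivity for one subject
#'
#' Each row of `zEdges` is the strict upper triangle (row-major, diagonal
#' excluded) of the Fisher-z transformed Pearson correlation matrix computed
#' in one sliding window.
#'
#' @slot subjectID subject identifier.
#' @slot L window length in volumes.
#' @slot s sliding step in volumes.
#' @slot zEdges numeric W x E matrix, E = P(P-1)/2 edges.
#' @slot windowStarts 1-based start index of each window.
#' @slot regionIDs region identifiers of the source series.
#'
#' @exportClass WindowedFCStack
setClass("WindowedFCStack",
  representation(
    subjectID    = "character",
    L            = "integer",
    s            = "integer",
    zEdges       = "matrix",
    windowStarts = "integer",
    regionIDs    = "character"
  )
)

setValidity("WindowedFCStack", function(object) {
  msg <- character()
  P <- length(object@regionIDs)
  if (ncol(object@zEdges) != P * (P - 1L) / 2L)
    msg <- c(msg, "zEdges columns must equal P(P-1)/2")
  if (nrow(object@zEdges) != length(object@windowStarts))
    msg <- c(msg, "one window start per window")
  if (any(!is.finite(object@zEdges)))
    msg <- c(msg, "all Fisher-z values must be finite (clip before atanh)")
  if (object@L < 3L) msg <- c(msg, "window length must be >= 3")
  if (object@s < 1L) msg <- c(msg, "step must be >= 1")
  if (length(msg)) msg else TRUE
})

#' StateModel: k-means decomposition of pooled windowed connectivity
#'
#' @slot k number of states.
#' @slot centroids k x E matrix of state centroids in edge space.
#' @slot labels named list: per subject, the integer state label of each
#'   window (values in 1..k).
#' @slot SSE total within-cluster sum of squared errors at `k`.
#' @slot selection data.frame with one row per candidate k (columns
#'   `k`, `SSE`, `silhouette`, `CH`) when produced by [selectK()].
#' @slot regionIDs region identifiers defining the edge order.
#' @slot seed integer seed used for the fit.
#'
#' @exportClass StateModel
setClass("StateModel",
  representation(
    k         = "integer",
    centroids = "matrix",
    labels    = "list",
    SSE       = "numeric",
    selection = "data.frame",
    regionIDs = "character",
    seed      = "integer"
  )
)

setValidity("StateModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@k) msg <- c(msg, "one centroid per state")
  lab <- unlist(object@labels, use.names = FALSE)
  if (length(lab) && (min(lab) < 1L || max(lab) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' GradientSet: diffusion-map gradient components for one embedding
#'
#' @slot components n_voxels x n_components matrix of gradient scores,
#'   ordered by non-increasing eigenvalue.
#' @slot eigenvalues eigenvalues of the diffusion operator, non-increasing,
#'   trivial (unit) eigenvalue excluded.
#' @slot aligned has Procrustes alignment to a template been applied?
#' @slot zscored have components been standardized across voxels?
#' @slot alpha anisotropic diffusion normalization exponent.
#' @slot t diffusion time (0 selects the lambda/(1-lambda) scaling).
#'
#' @exportClass GradientSet
setClass("GradientSet",
  representation(
    components  = "matrix",
    eigenvalues = "numeric",
    aligned     = "logical",
    zscored     = "logical",
    alpha       = "numeric",
    t           = "numeric"
  ),
  prototype(aligned = FALSE, zscored = FALSE, alpha = 0.5, t = 0)
)

setValidity("GradientSet", function(object) {
  msg <- character()
  if (ncol(object@components) != length(object@eigenvalues))
    msg <- c(msg, "one eigenvalue per component")
  ev <- object@eigenvalues
  if (length(ev) > 1L && !anyNA(ev) && any(diff(ev) > 1e-8))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' CVResult: cross-validated evaluation of one classifier
#'
#' @slot classifier classifier name.
#' @slot scheme `"loocv"` or `"5fold"`.
#' @slot predictions data.frame with one row per evaluated subject:
#'   `subject`, `fold`, `truth`, `predicted`, `score` (decision score for the
#'   positive class).
#' @slot counts named integer vector `TP`, `FP`, `TN`, `FN`.
#' @slot metrics named numeric vector `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `auc`.
#' @slot roc data.frame of pooled ROC points (`fpr`, `tpr`, `threshold`).
#' @slot scaling data.frame of per-fold training-set standardization
#'   parameters (leakage audit trail).
#' @slot seed integer seed.
#'
#' @exportClass CVResult
setClass("CVResult",
  representation(
    classifier  = "character",
    scheme      = "character",
    predictions = "data.frame",
    counts      = "integer",
    metrics     = "numeric",
    roc         = "data.frame",
    scaling     = "data.frame",
    seed        = "integer"
  )
)

setValidity("CVResult", function(object) {
  msg <- character()
  if (!all(c("TP", "FP", "TN", "FN") %in% names(object@counts)))
    msg <- c(msg, "counts must name TP, FP, TN, FN")
  if (sum(object@counts) != nrow(object@predictions))
    msg <- c(msg, "confusion counts must sum to the number of evaluated subjects")
  au <- object@metrics[["auc"]]
  if (!is.na(au) && (au < 0 || au > 1)) msg <- c(msg, "AUC must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "SubjectTimeSeries", function(object) {
  cat("SubjectTimeSeries", object@subjectID,
      sprintf("(%s): %d volumes x %d regions, TR = %g s\n",
              object@group, nrow(object@data), ncol(object@data), object@TR))
})

setMethod("show", "WindowedFCStack", function(object) {
  cat("WindowedFCStack", object@subjectID,
      sprintf(": %d windows (L = %d, step = %d) x %d edges\n",
              nrow(object@zEdges), object@L, object@s, ncol(object@zEdges)))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel: k = %d states, %d edges, %d subjects, SSE = %.4g\n",
              object@k, ncol(object@centroids), length(object@labels),
              object@SSE))
  if (nrow(object@selection))
    cat("  selection table over k =",
        paste(range(object@selection$k), collapse = ".."), "\n")
})

setMethod("show", "GradientSet", function(object) {
  cat(sprintf("GradientSet: %d voxels x %d components (alpha = %g, t = %g)%s%s\n",
              nrow(object@components), ncol(object@components),
              object@alpha, object@t,
              if (object@aligned) ", aligned" else "",
              if (object@zscored) ", z-scored" else ""))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %s under %s (n = %d)\n", object@classifier,
              object@scheme, nrow(object@predictions)))
  print(round(object@metrics, 3))
})

## ---- accessors ----

#' @rdname accessors
#' @param object an object of one of the package's classes.
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("tsData", function(object) standardGeneric("tsData"))
#' @rdname accessors
#' @export
setGeneric("regionIDs", function(object) standardGeneric("regionIDs"))
#' @rdname accessors
#' @export
setGeneric("zEdges", function(object) standardGeneric("zEdges"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("selectionTable", function(object) standardGeneric("selectionTable"))
#' @rdname accessors
#' @export
setGeneric("gradientComponents", function(object) standardGeneric("gradientComponents"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("cvMetrics", function(object) standardGeneric("cvMetrics"))
#' @rdname accessors
#' @export
setGeneric("cvPredictions", function(object) standardGeneric("cvPredictions"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))

#' Accessors for the package's S4 classes
#'
#' Slot access for user code; slots themselves are not part of the API.
#'
#' @name accessors
#' @rdname accessors
setMethod("subjectID", "SubjectTimeSeries", function(object) object@subjectID)
#' @rdname accessors
setMethod("subjectID", "WindowedFCStack", function(object) object@subjectID)
#' @rdname accessors
setMethod("groupLabel", "SubjectTimeSeries", function(object) object@group)
#' @rdname accessors
setMethod("tsData", "SubjectTimeSeries", function(object) object@data)
#' @rdname accessors
setMethod("regionIDs", "SubjectTimeSeries", function(object) object@regionIDs)
#' @rdname accessors
setMethod("regionIDs", "WindowedFCStack", function(object) object@regionIDs)
#' @rdname accessors
setMethod("regionIDs", "StateModel", function(object) object@regionIDs)
#' @rdname accessors
setMethod("zEdges", "WindowedFCStack", function(object) object@zEdges)
#' @rdname accessors
setMethod("stateLabels", "StateModel", function(object) object@labels)
#' @rdname accessors
setMethod("centroids", "StateModel", function(object) object@centroids)
#' @rdname accessors
setMethod("selectionTable", "StateModel", function(object) object@selection)
#' @rdname accessors
setMethod("gradientComponents", "GradientSet", function(object) object@components)
#' @rdname accessors
setMethod("eigenvalues", "GradientSet", function(object) object@eigenvalues)
#' @rdname accessors
setMethod("cvMetrics", "CVResult", function(object) object@metrics)
#' @rdname accessors
setMethod("cvPredictions", "CVResult", function(object) object@predictions)
#' @rdname accessors
setMethod("confusionCounts", "CVResult", function(object) object@counts)
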