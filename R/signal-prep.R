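# File formats and the two time-series conditioning steps the pipeline owns.
#
# Time series: TSV, rows = time, header = region ids.  Manifest: CSV.
# Network map: TSV (region_id, network).  All text is UTF-8 with "." decimal.

.minFilterLength <- function(order) 12L * order  # filtfilt transient guard

# zero-phase Butterworth band-pass applied column-wise to a T x P matrix
.butterBandpass <- function(X, low, high, TR, order = 4L) {
  nyq <- 1 / (2 * TR)
  if (low <= 0 || high <= low) .stopf("need 0 < low < high")
  if (high >= nyq) .stopf("high edge %.4g Hz is at or above Nyquist (%.4g Hz)",
                          high, nyq)
  if (nrow(X) < .minFilterLength(order))
    .stopf("series of length %d too short for an order-%d zero-phase filter",
           nrow(X), order)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  apply(X, 2, function(col) signal::filtfilt(bf, col))
}

#' Remove a per-region polynomial trend
#'
#' Least-squares removal of an order-0 (mean) or order-1 (linear) trend from
#' each region's series; the returned columns have mean zero.  A constant
#' column simply becomes zero.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @param order 0 (demean) or 1 (demean + linear detrend).
#' @return the detrended [SubjectTimeSeries-class].
#' @export
detrendTS <- function(ts, order = 1L) {
  stopifnot(is(ts, "SubjectTimeSeries"), order %in% c(0L, 1L))
  X <- tsData(ts)
  if (nrow(X) <= order + 1L) .stopf("need more than %d time points", order + 1L)
  tIdx <- seq_len(nrow(X))
  basis <- if (order == 0L) cbind(rep(1, nrow(X))) else cbind(1, tIdx)
  fit <- basis %*% qr.coef(qr(basis), X)
  Y <- X - fit
  initialize(ts, data = `colnames<-`(Y, regionIDs(ts)))
}

#' Band-pass filter a subject's time series
#'
#' Zero-phase (forward-backward) Butterworth filtering of each region's
#' series; the default 0.01-0.08 Hz band retains the slow fluctuations
#' conventionally analyzed in resting-state BOLD.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @param low,high band edges in Hz; `high` must be below Nyquist = 1/(2 TR).
#' @param order Butterworth order of the single-pass prototype (the
#'   zero-phase application doubles the effective order).
#' @return the filtered [SubjectTimeSeries-class].
#' @export
bandpassTS <- function(ts, low = 0.01, high = 0.08, order = 4L) {
  stopifnot(is(ts, "SubjectTimeSeries"))
  Y <- .butterBandpass(tsData(ts), low, high, ts@TR, order)
  initialize(ts, data = `colnames<-`(Y, regionIDs(ts)))
}

#' Write a cohort to disk
#'
#' One TSV per subject (rows = time, header = region ids), a manifest CSV,
#' a region-to-network TSV, and - when generative truth is present - a
#' ground-truth JSON (true state sequences, planted effects).
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "Cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsdir <- file.path(dir, "timeseries")
  dir.create(tsdir, showWarnings = FALSE)
  clin <- clinicalTable(cohort)
  files <- character(nrow(clin))
  for (i in seq_along(cohort@subjects)) {
    sb <- cohort@subjects[[i]]
    files[i] <- file.path("timeseries", paste0(subjectID(sb), ".tsv"))
    utils::write.table(tsData(sb), file.path(dir, files[i]),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  man <- cbind(clin, file = files, TR = vapply(cohort@subjects, slot, numeric(1), "TR"))
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE, quote = FALSE)
  utils::write.table(networkMap(cohort), file.path(dir, "network_map.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  tr <- cohortTruth(cohort)
  if (length(tr)) {
    truth <- list(states = tr$states, effectEdges = tr$effectEdges,
                  transition = tr$model$transition)
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manPath)
}

#' Load a cohort from a manifest
#'
#' Subjects are returned in manifest order; every subject's columns are
#' re-ordered to the first subject's region order, and a region mismatch or
#' a non-numeric cell is reported with the offending subject/location.
#'
#' @param manifestPath manifest CSV with at least `subject_id`, `group`,
#'   `file` columns (a `TR` column is honored, default 2 s).
#' @param dir directory against which relative `file` entries are resolved;
#'   defaults to the manifest's directory.
#' @param networkMapPath optional region-to-network TSV.
#' @return a [Cohort-class] (empty `truth`).
#' @export
loadCohort <- function(manifestPath, dir = dirname(manifestPath),
                       networkMapPath = NULL) {
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "file")
  if (!all(need %in% names(man)))
    .stopf("manifest must contain columns: %s", paste(need, collapse = ", "))
  canonical <- NULL
  subjects <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    path <- man$file[i]
    if (!file.exists(path)) path <- file.path(dir, man$file[i])
    if (!file.exists(path))
      .stopf("time-series file missing for subject %s: %s",
             man$subject_id[i], man$file[i])
    X <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
    bad <- which(!vapply(X, is.numeric, logical(1)))
    if (length(bad))
      .stopf("non-numeric values for subject %s in column '%s'",
             man$subject_id[i], names(X)[bad[1]])
    X <- as.matrix(X)
    if (is.null(canonical)) canonical <- colnames(X)
    if (!setequal(colnames(X), canonical))
      .stopf("region ids of subject %s do not match the cohort's regions",
             man$subject_id[i])
    X <- X[, canonical, drop = FALSE]
    TR <- if ("TR" %in% names(man)) man$TR[i] else 2
    subjects[[i]] <- SubjectTimeSeries(man$subject_id[i], man$group[i],
                                       X, TR = TR, regionIDs = canonical)
  }
  nm <- if (!is.null(networkMapPath)) {
    utils::read.table(networkMapPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else data.frame(region_id = character(0), network = character(0))
  clin <- man[, setdiff(names(man), c("file", "TR")), drop = FALSE]
  new("Cohort", subjects = subjects, clinical = clin, networkMap = nm,
      truth = list())
}
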