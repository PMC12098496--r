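# Shared fixtures and independent oracles, all built in code.

# a WindowedFCStack directly from an edge matrix (bypasses windowing)
stackFromZ <- function(Z, id = "sub-x", P = NULL, L = 3L, s = 1L) {
  if (is.null(P)) P <- (1 + sqrt(1 + 8 * ncol(Z))) / 2
  new("WindowedFCStack", subjectID = id, L = as.integer(L), s = as.integer(s),
      zEdges = Z, windowStarts = seq_len(nrow(Z)) * s - s + 1L,
      regionIDs = sprintf("R%02d", seq_len(P)))
}

# a StateModel directly from per-subject label vectors
modelFromLabels <- function(labels, k, E = 3L) {
  new("StateModel", k = as.integer(k),
      centroids = matrix(0, k, E), labels = labels,
      SSE = 0, selection = data.frame(),
      regionIDs = sprintf("R%02d", seq_len((1 + sqrt(1 + 8 * E)) / 2)),
      seed = 1L)
}

# brute-force run-length oracle for state dynamics
bruteDynamics <- function(lab, k) {
  W <- length(lab)
  runs <- integer(0); vals <- integer(0)
  cur <- lab[1]; len <- 1L
  for (t in seq_len(W)[-1]) {
    if (lab[t] == cur) len <- len + 1L
    else { runs <- c(runs, len); vals <- c(vals, cur); cur <- lab[t]; len <- 1L }
  }
  runs <- c(runs, len); vals <- c(vals, cur)
  list(
    occupancy = vapply(seq_len(k), function(j) sum(lab == j) / W, numeric(1)),
    dwell = vapply(seq_len(k), function(j)
      if (any(vals == j)) mean(runs[vals == j]) else NA_real_, numeric(1)),
    transitions = length(runs) - 1L)
}

# Mann-Whitney rank-statistic AUC oracle (ties counted half)
rankAUC <- function(score, truth01) {
  pos <- score[truth01 == 1]; neg <- score[truth01 == 0]
  gr <- outer(pos, neg, ">"); eq <- outer(pos, neg, "==")
  (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# small two-state planted cohort for recovery tests
plantedCohort <- function(nPerGroup = 8, P = 30, T = 200, seed = 1,
                          nStates = 4, stickiness = 0.9) {
  spec <- cohortSpec(nPatients = nPerGroup, nControls = nPerGroup, T = T,
                     P = P, nStates = nStates, stickiness = stickiness,
                     seed = seed)
  simulateCohort(spec, clinical = NULL)
}

# window-level truth: majority planted state within each window
windowTruth <- function(states, L, s) {
  W <- (length(states) - L) %/% s + 1L
  vapply(seq_len(W), function(w) {
    idx <- ((w - 1L) * s + 1L):((w - 1L) * s + L)
    which.max(tabulate(states[idx]))
  }, integer(1))
}
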