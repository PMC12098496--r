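# Synthetic two-group cohort generator.
#
# The generative model is a Markov-switching Gaussian: each subject carries a
# hidden state sequence (k states, sticky transitions), every volume is drawn
# from the active state's covariance, AR(1)-colored in time, and band-pass
# filtered.  Group effects are planted as Fisher-z shifts on designated
# region-pair covariances (patients only).  A separate one-dimensional latent
# manifold generates voxel-level connectivity profiles for the gradient
# track, with patient-only coordinate shifts in designated regions.

#' Cohort container
#'
#' Bundles simulated (or loaded) subjects with their clinical table, the
#' region-to-network map, and - for synthetic cohorts - the generative ground
#' truth used by recovery tests.
#'
#' @slot subjects list of [SubjectTimeSeries-class].
#' @slot clinical data.frame, one row per subject.
#' @slot networkMap data.frame with columns `region_id`, `network`.
#' @slot truth list of ground-truth elements (empty for loaded cohorts).
#' @exportClass Cohort
setClass("Cohort",
  representation(subjects = "list", clinical = "data.frame",
                 networkMap = "data.frame", truth = "list"))

setValidity("Cohort", function(object) {
  ok <- vapply(object@subjects, is, logical(1), class2 = "SubjectTimeSeries")
  if (!all(ok)) return("subjects must all be SubjectTimeSeries")
  TRUE
})

setMethod("show", "Cohort", function(object) {
  gr <- vapply(object@subjects, groupLabel, character(1))
  cat(sprintf("Cohort: %d subjects (%d patients, %d controls)\n",
              length(gr), sum(gr == "patient"), sum(gr == "control")))
})

#' @rdname accessors
#' @export
setGeneric("cohortSubjects", function(object) standardGeneric("cohortSubjects"))
#' @rdname accessors
setMethod("cohortSubjects", "Cohort", function(object) object@subjects)
#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(object) standardGeneric("clinicalTable"))
#' @rdname accessors
setMethod("clinicalTable", "Cohort", function(object) object@clinical)
#' @rdname accessors
#' @export
setGeneric("networkMap", function(object) standardGeneric("networkMap"))
#' @rdname accessors
setMethod("networkMap", "Cohort", function(object) object@networkMap)
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @rdname accessors
setMethod("cohortTruth", "Cohort", function(object) object@truth)

#' The seven canonical cortical network labels (plus subcortex)
#' @return character vector of the 7 network names used throughout.
#' @export
yeoNetworkNames <- function() {
  c("visual", "somatomotor", "dorsal attention", "ventral attention",
    "limbic", "frontoparietal", "default mode")
}

.defaultNetworkMap <- function(regionIDs) {
  nets <- c(yeoNetworkNames(), "subcortical")
  data.frame(region_id = regionIDs,
             network = rep(nets, length.out = length(regionIDs)),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic dynamic-connectivity cohort
#'
#' Defaults emulate the study design the package targets: 34 patients vs 32
#' controls, 200 retained volumes at TR = 2 s, band-limited 0.01-0.08 Hz
#' signal, and 4 sticky Markov covariance states.
#'
#' @param nPatients,nControls group sizes.
#' @param T volumes per subject.
#' @param TR repetition time, seconds.
#' @param P number of regions.
#' @param nStates number of planted covariance states (>= 2).
#' @param stickiness Markov self-transition probability in `[0, 1)`.
#' @param arPhi AR(1) temporal coloring coefficient in `[0, 1)`.
#' @param withinRho within-module correlation of the modular base pattern
#'   shared by all states.
#' @param nModules modules in the shared base pattern.
#' @param stateFactorWeight weight w of each state's rank-one sign-factor
#'   component (see [generateStateModel()]); with the default 0.4 the
#'   pairwise centroid separation on the Fisher-z scale clears the
#'   window-noise floor for any region count.
#' @param effectEdges data.frame (`i`, `j`, `zShift`): patient-only Fisher-z
#'   covariance shifts on region pairs. `NULL` uses a default set of
#'   default-mode/somatomotor pairs (three positive shifts, one negative,
#'   |z| = 0.5), sized for detectability at n = 66.
#' @param band band-pass edges in Hz (`NULL` to skip filtering).
#' @param separationFloor minimum pairwise distance between state
#'   covariances on the Fisher-z edge scale; `NULL` derives it from the
#'   window-noise scale (see [generateStateModel()]).
#' @param seed master seed; all subject-level draws derive from it.
#' @return A `CohortSpec` (validated list).
#' @export
cohortSpec <- function(nPatients = 34, nControls = 32, T = 200, TR = 2,
                       P = 90, nStates = 4, stickiness = 0.9, arPhi = 0.3,
                       withinRho = 0.35, nModules = 3, effectEdges = NULL,
                       band = c(0.01, 0.08), separationFloor = NULL,
                       stateFactorWeight = 0.4, seed = 1L) {
  if (nPatients + nControls < 4) .stopf("need at least 4 subjects in total")
  if (stickiness < 0 || stickiness >= 1) .stopf("stickiness must lie in [0, 1)")
  if (arPhi < 0 || arPhi >= 1) .stopf("arPhi must lie in [0, 1)")
  if (nStates < 2) .stopf("need at least 2 states")
  if (P < 4) .stopf("need at least 4 regions")
  regionIDs <- sprintf("R%03d", seq_len(P))
  nm <- .defaultNetworkMap(regionIDs)
  if (is.null(effectEdges)) {
    dmn <- which(nm$network == "default mode")
    smn <- which(nm$network == "somatomotor")
    if (length(dmn) < 2 || length(smn) < 2) {  # tiny P: fall back to leading regions
      dmn <- c(1L, 2L); smn <- c(3L, 4L)
    }
    effectEdges <- data.frame(
      i = c(dmn[1], dmn[2], dmn[1], dmn[2]),
      j = c(smn[1], smn[1], smn[2], smn[2]),
      zShift = c(0.5, 0.5, 0.5, -0.5))
  }
  if (nrow(effectEdges) &&
      (any(effectEdges$i < 1 | effectEdges$i > P) ||
       any(effectEdges$j < 1 | effectEdges$j > P) ||
       any(effectEdges$i == effectEdges$j)))
    .stopf("effect edges must reference distinct valid region pairs")
  if (stateFactorWeight < 0 || stateFactorWeight >= 1)
    .stopf("stateFactorWeight must lie in [0, 1)")
  if (is.null(separationFloor)) {
    # per-edge Fisher-z noise SD of a band-limited 100 s window is ~0.27;
    # demand pairwise centroid separation of twice the noise norm
    E <- P * (P - 1) / 2
    separationFloor <- 2 * sqrt(E) * 0.27
  }
  structure(list(nPatients = as.integer(nPatients),
                 nControls = as.integer(nControls),
                 T = as.integer(T), TR = TR, P = as.integer(P),
                 nStates = as.integer(nStates), stickiness = stickiness,
                 arPhi = arPhi, withinRho = withinRho,
                 nModules = as.integer(nModules),
                 stateFactorWeight = stateFactorWeight,
                 effectEdges = effectEdges, band = band,
                 separationFloor = separationFloor,
                 regionIDs = regionIDs, networkMap = nm,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

.isSPD <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol
}

# Fisher-z distance between two correlation matrices over the strict
# upper triangle - the metric in which windowed k-means operates
.zDistance <- function(Ca, Cb) {
  za <- .fisherZ(.vecUT(Ca)); zb <- .fisherZ(.vecUT(Cb))
  sqrt(sum((za - zb)^2))
}

#' Generate the Markov-switching state model of a cohort
#'
#' Builds the k x k transition matrix (diagonal = stickiness, remaining mass
#' uniform off-diagonal) and k symmetric positive-definite state
#' correlation matrices of the form
#' `Sigma_j = (1 - w) B + w v_j v_j'`,
#' where `B` is a modular base pattern shared by all states (within-module
#' correlation `withinRho`) and `v_j` is a state-specific vector of +/-1
#' signs - one dominant connectivity mode per state, the way empirical
#' brain states differ in the topography of their leading FC component.
#' Two random sign patterns disagree on about half the edges, so the
#' pairwise centroid distance on the Fisher-z scale is ~ `2 atanh(w)
#' sqrt(E/2)`, which for the default w = 0.4 clears the configured
#' `separationFloor` at every region count.  A draw is rejected and redrawn
#' (with jitter on the sign pattern) if a covariance fails the
#' positive-definite check or a state pair falls within the floor; bounded
#' retries, then an error.
#'
#' @param spec a [cohortSpec()].
#' @param maxRetries bound on redraw attempts.
#' @return list with `transition` (k x k), `covariances` (list of P x P
#'   correlation matrices), and `signPatterns` (list of +/-1 vectors).
#' @export
generateStateModel <- function(spec, maxRetries = 20L) {
  stopifnot(inherits(spec, "CohortSpec"))
  k <- spec$nStates; P <- spec$P; w <- spec$stateFactorWeight
  trans <- matrix((1 - spec$stickiness) / (k - 1), k, k)
  diag(trans) <- spec$stickiness
  set.seed(.deriveSeed(spec$seed, 1L))
  # shared modular base
  part <- sample(rep(seq_len(spec$nModules), length.out = P))
  B <- diag(P)
  for (b in seq_len(spec$nModules)) {
    idx <- which(part == b)
    B[idx, idx] <- spec$withinRho
  }
  diag(B) <- 1
  covs <- vector("list", k); signs <- vector("list", k)
  for (j in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(maxRetries)) {
      v <- sample(c(-1, 1), P, replace = TRUE)
      C <- (1 - w) * B + w * tcrossprod(v)
      diag(C) <- 1
      sep <- if (j == 1) TRUE else
        all(vapply(covs[seq_len(j - 1)], .zDistance, numeric(1), Ca = C) >=
              spec$separationFloor)
      if (.isSPD(C) && sep) { ok <- TRUE; break }
    }
    if (!ok) .stopf("failed to construct state covariance %d after %d retries",
                    j, maxRetries)
    covs[[j]] <- C; signs[[j]] <- v
  }
  list(transition = trans, covariances = covs, signPatterns = signs,
       basePartition = part)
}

# apply patient effect edges on the Fisher-z scale, then repair SPD by
# eigenvalue clipping if the shift broke positive-definiteness
.applyEffectEdges <- function(C, effectEdges) {
  if (!nrow(effectEdges)) return(C)
  for (r in seq_len(nrow(effectEdges))) {
    i <- effectEdges$i[r]; j <- effectEdges$j[r]
    z <- atanh(pmin(pmax(C[i, j], -.CLIP), .CLIP)) + effectEdges$zShift[r]
    C[i, j] <- C[j, i] <- tanh(z)
  }
  if (!.isSPD(C)) {
    e <- eigen(C, symmetric = TRUE)
    ev <- pmax(e$values, 1e-6)
    C <- e$vectors %*% (ev * t(e$vectors))
    D <- 1 / sqrt(diag(C))
    C <- C * tcrossprod(D)
  }
  C
}

#' Simulate one subject's BOLD time series
#'
#' Samples the hidden Markov state sequence, draws each volume from the
#' active state's covariance, applies AR(1) temporal coloring, band-pass
#' filters each region's series, and returns both the time series and the
#' true state sequence (for recovery tests).  Patient subjects receive the
#' spec's `effectEdges` covariance shifts; controls do not.
#'
#' @param spec a [cohortSpec()].
#' @param group `"patient"` or `"control"`.
#' @param model output of [generateStateModel()].
#' @param seed integer seed for this subject.
#' @param subjectID identifier.
#' @return list with `ts` ([SubjectTimeSeries-class]) and `states`
#'   (integer vector of length T).
#' @export
simulateSubject <- function(spec, group, model, seed,
                            subjectID = sprintf("sub-%05d", seed %% 100000L)) {
  stopifnot(inherits(spec, "CohortSpec"))
  group <- match.arg(group, c("patient", "control"))
  k <- spec$nStates; P <- spec$P; Tn <- spec$T
  if (!is.null(spec$band) && Tn < .minFilterLength(4L))
    .stopf("T = %d is shorter than the band-pass filter transient", Tn)
  covs <- model$covariances
  if (group == "patient")
    covs <- lapply(covs, .applyEffectEdges, effectEdges = spec$effectEdges)
  chols <- lapply(covs, chol)
  .seedStream(seed)
  states <- integer(Tn)
  states[1] <- sample.int(k, 1)
  for (t in 2:Tn)
    states[t] <- sample.int(k, 1, prob = model$transition[states[t - 1], ])
  eps <- matrix(stats::rnorm(Tn * P), Tn, P)
  X <- matrix(0, Tn, P)
  phi <- spec$arPhi
  for (t in seq_len(Tn)) {
    innov <- eps[t, , drop = FALSE] %*% chols[[states[t]]]
    X[t, ] <- if (t == 1) innov else phi * X[t - 1, ] + sqrt(1 - phi^2) * innov
  }
  if (!is.null(spec$band))
    X <- .butterBandpass(X, spec$band[1], spec$band[2], spec$TR)
  ts <- SubjectTimeSeries(subjectID, group, X, TR = spec$TR,
                          regionIDs = spec$regionIDs)
  list(ts = ts, states = states)
}

#' Simulate a full cohort
#'
#' Patients first, controls second; per-subject seeds derive from the spec's
#' master seed so any subset is reproducible.
#'
#' @param spec a [cohortSpec()].
#' @param model optional pre-built state model; generated from the spec
#'   when omitted.
#' @param clinical optional [clinicalSpec()]; when supplied a clinical table
#'   is generated (without gradient-score mixing - see [generateClinical()]).
#' @return A [Cohort-class]; `cohortTruth()` carries the state model and the
#'   per-subject true state sequences.
#' @export
simulateCohort <- function(spec, model = NULL, clinical = clinicalSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (is.null(model)) model <- generateStateModel(spec)
  n <- spec$nPatients + spec$nControls
  groups <- rep(c("patient", "control"), c(spec$nPatients, spec$nControls))
  ids <- sprintf("sub-%03d", seq_len(n))
  subjects <- vector("list", n); states <- vector("list", n)
  subjSeeds <- .seedBlock(.deriveSeed(spec$seed, 2L), n)
  for (i in seq_len(n)) {
    sim <- simulateSubject(spec, groups[i], model, seed = subjSeeds[i],
                           subjectID = ids[i])
    subjects[[i]] <- sim$ts; states[[i]] <- sim$states
  }
  names(states) <- ids
  clin <- if (is.null(clinical)) {
    data.frame(subject_id = ids, group = groups, stringsAsFactors = FALSE)
  } else {
    generateClinical(clinical, ids, groups,
                     seed = .deriveSeed(spec$seed, 7L))
  }
  new("Cohort", subjects = subjects, clinical = clin,
      networkMap = spec$networkMap,
      truth = list(model = model, states = states,
                   effectEdges = spec$effectEdges))
}

## ---- gradient-track manifold ----

#' Specification of the synthetic connectivity manifold for one network
#'
#' Voxels live on a smooth 1-D latent coordinate in `[0, 1]`; each voxel's
#' connectivity profile across the cortical parcels is a smooth function of
#' that coordinate, so nearby voxels have more similar profiles.  Patients
#' receive an additive profile perturbation (the profile difference induced
#' by a latent-coordinate offset) in designated regions.
#'
#' @param nVoxels voxels in the network (>= 50).
#' @param nParcels cortical parcels (default 400).
#' @param smoothness correlation length of profiles on the latent axis (> 0).
#' @param noiseSD per-entry profile noise SD.
#' @param subjectSD between-subject variability of the latent axis: each
#'   subject's coordinates are smoothly warped as
#'   `c' = 0.5 + (1 + a)(c - 0.5) + b` with global shift
#'   `b ~ N(0, subjectSD)` and stretch `a ~ N(0, 2 subjectSD)`.  A smooth
#'   warp (rather than independent regional offsets) keeps the manifold
#'   connected while making regional gradient scores vary across subjects,
#'   so group inference is non-trivial.
#' @param nRegions contiguous anatomical-style subregions of the network.
#' @param groupShiftRegions named numeric vector: region name ->
#'   latent-coordinate offset applied to patients.
#' @param seed master seed for profile noise.
#' @return A `GradientManifoldSpec` (validated list).
#' @export
gradientManifoldSpec <- function(nVoxels = 200, nParcels = 400,
                                 smoothness = 0.1, noiseSD = 0.1,
                                 subjectSD = 0.05, nRegions = 8,
                                 groupShiftRegions = numeric(0),
                                 seed = 1L) {
  if (nVoxels < 50) .stopf("need at least 50 voxels")
  if (smoothness <= 0) .stopf("smoothness must be positive")
  regions <- sprintf("reg%02d", seq_len(nRegions))
  if (length(groupShiftRegions) &&
      !all(names(groupShiftRegions) %in% regions))
    .stopf("unknown shift region(s): %s",
           paste(setdiff(names(groupShiftRegions), regions), collapse = ", "))
  # latent coordinates: ascending, equally spaced in (0,1)
  latent <- (seq_len(nVoxels) - 0.5) / nVoxels
  regionOf <- regions[ceiling(seq_len(nVoxels) / nVoxels * nRegions)]
  structure(list(nVoxels = as.integer(nVoxels),
                 nParcels = as.integer(nParcels),
                 smoothness = smoothness, noiseSD = noiseSD,
                 subjectSD = subjectSD,
                 regions = regions, regionOf = regionOf,
                 latent = latent,
                 groupShiftRegions = groupShiftRegions,
                 seed = as.integer(seed)),
            class = "GradientManifoldSpec")
}

.manifoldProfile <- function(coord, parcelPos, smoothness) {
  # smooth bump: correlation of a voxel at `coord` with each parcel
  0.5 * exp(-outer(coord, parcelPos, "-")^2 / (2 * smoothness^2))
}

#' Simulate one subject's voxel-by-parcel connectivity for a network
#'
#' @param mspec a [gradientManifoldSpec()].
#' @param group `"patient"` or `"control"`.
#' @param seed integer seed for this subject's profile noise.
#' @return list with `fc` (nVoxels x nParcels Fisher-z matrix), `latent`
#'   (true coordinates actually used, after any patient shift), `region`
#'   (voxel region labels).
#' @export
simulateNetworkVoxels <- function(mspec, group, seed) {
  stopifnot(inherits(mspec, "GradientManifoldSpec"))
  group <- match.arg(group, c("patient", "control"))
  .seedStream(seed)
  coord <- mspec$latent
  if (mspec$subjectSD > 0) {
    # smooth per-subject warp of the latent axis: shift + stretch + bend.
    # The quadratic term matters: per-subject z-scoring of gradient scores
    # absorbs (near-)affine warps, so without it between-subject variance
    # of regional scores would collapse to the profile-noise floor.
    b <- stats::rnorm(1, sd = mspec$subjectSD)
    a <- stats::rnorm(1, sd = 2 * mspec$subjectSD)
    q <- stats::rnorm(1, sd = 4 * mspec$subjectSD)
    coord <- coord + b + a * (coord - 0.5) + q * (coord - 0.5)^2
  }
  if (group == "patient" && length(mspec$groupShiftRegions)) {
    for (rg in names(mspec$groupShiftRegions)) {
      idx <- which(mspec$regionOf == rg)
      coord[idx] <- coord[idx] + mspec$groupShiftRegions[[rg]]
    }
  }
  coord <- pmin(pmax(coord, 0), 1)
  parcelPos <- (seq_len(mspec$nParcels) - 0.5) / mspec$nParcels
  r <- .manifoldProfile(coord, parcelPos, mspec$smoothness)
  if (mspec$noiseSD > 0) {
    r <- r + matrix(stats::rnorm(length(r), sd = mspec$noiseSD),
                    nrow(r), ncol(r))
  }
  fc <- .fisherZ(pmin(pmax(r, -0.95), 0.95))
  rownames(fc) <- sprintf("vox%04d", seq_len(mspec$nVoxels))
  colnames(fc) <- sprintf("parcel%03d", seq_len(mspec$nParcels))
  list(fc = fc, latent = coord, region = mspec$regionOf)
}

## ---- clinical table ----

#' Specification of the clinical covariates
#'
#' Defaults emulate the demographic structure the package targets: patients
#' aged 10.41 +/- 1.376 years, controls 11.28 +/- 2.439 years, Wechsler-style
#' scores for patients only, disease duration with a right-skewed
#' distribution around a median of 1 year.
#'
#' @param ageMeans,ageSDs named numeric (patient, control), years.
#' @param pFemale named numeric: probability a subject is female per group.
#' @param scoreMeans,scoreSDs named numeric over the five cognitive scores.
#' @param durationMeanlog,durationSdlog log-normal parameters of disease
#'   duration in years (patients only).
#' @param plantedCorrelations data.frame (`score`, `region`, `r`): mix the
#'   named region's gradient score into the named clinical score so the
#'   population correlation equals `r`.
#' @return A `ClinicalSpec` (validated list).
#' @export
clinicalSpec <- function(
    ageMeans = c(patient = 10.41, control = 11.28),
    ageSDs   = c(patient = 1.376, control = 2.439),
    pFemale  = c(patient = 19 / 34, control = 14 / 32),
    scoreMeans = c(verbal_comprehension = 31.41, perceptual_processing = 26,
                   working_memory = 19.56, processing_speed = 19,
                   full_scale = 97.68),
    scoreSDs = c(verbal_comprehension = 11.293, perceptual_processing = 11,
                 working_memory = 4.825, processing_speed = 4.4,
                 full_scale = 23.708),
    durationMeanlog = 0, durationSdlog = 0.7,
    plantedCorrelations = NULL) {
  if (any(ageSDs <= 0) || any(scoreSDs <= 0)) .stopf("SDs must be positive")
  if (!is.null(plantedCorrelations)) {
    if (any(abs(plantedCorrelations$r) >= 1)) .stopf("|target r| must be < 1")
    unknown <- setdiff(plantedCorrelations$score, names(scoreMeans))
    if (length(unknown)) .stopf("unknown score name(s): %s",
                                paste(unknown, collapse = ", "))
  }
  structure(list(ageMeans = ageMeans, ageSDs = ageSDs, pFemale = pFemale,
                 scoreMeans = scoreMeans, scoreSDs = scoreSDs,
                 durationMeanlog = durationMeanlog,
                 durationSdlog = durationSdlog,
                 plantedCorrelations = plantedCorrelations),
            class = "ClinicalSpec")
}

#' Generate the clinical covariate table
#'
#' Ages and sex are drawn per group; Wechsler-style scores and disease
#' duration for patients only.  When `plantedCorrelations` name a gradient
#' region, that region's (standardized) gradient score is mixed into the
#' clinical score at weight r vs sqrt(1 - r^2) noise, so the population
#' correlation equals the target.
#'
#' @param cspec a [clinicalSpec()].
#' @param subjectIDs,groups aligned vectors describing the cohort.
#' @param gradientScores optional data.frame (`subject_id`, `region`,
#'   `score`) of per-subject regional gradient scores; required if planted
#'   correlations are requested.
#' @param seed integer seed.
#' @return data.frame: subject_id, group, age, sex (0 = male, 1 = female),
#'   duration_years, and the five scores (NA for controls).
#' @export
generateClinical <- function(cspec, subjectIDs, groups,
                             gradientScores = NULL, seed = 1L) {
  stopifnot(inherits(cspec, "ClinicalSpec"))
  set.seed(seed)
  n <- length(subjectIDs)
  pat <- groups == "patient"
  age <- ifelse(pat,
                stats::rnorm(n, cspec$ageMeans["patient"], cspec$ageSDs["patient"]),
                stats::rnorm(n, cspec$ageMeans["control"], cspec$ageSDs["control"]))
  sex <- ifelse(pat,
                stats::rbinom(n, 1, cspec$pFemale["patient"]),
                stats::rbinom(n, 1, cspec$pFemale["control"]))
  dur <- ifelse(pat,
                stats::rlnorm(n, cspec$durationMeanlog, cspec$durationSdlog),
                NA_real_)
  out <- data.frame(subject_id = subjectIDs, group = groups,
                    age = age, sex = sex, duration_years = dur,
                    stringsAsFactors = FALSE)
  planted <- cspec$plantedCorrelations
  for (sc in names(cspec$scoreMeans)) {
    mu <- cspec$scoreMeans[[sc]]; sd <- cspec$scoreSDs[[sc]]
    noise <- stats::rnorm(n)
    val <- rep(NA_real_, n)
    row <- if (is.null(planted)) integer(0) else which(planted$score == sc)
    if (length(row)) {
      if (length(row) > 1)
        .stopf("multiple planted correlations for score '%s'", sc)
      if (is.null(gradientScores))
        .stopf("planted correlation for '%s' requires gradientScores", sc)
      reg <- planted$region[row]; r <- planted$r[row]
      gs <- gradientScores[gradientScores$region == reg, ]
      if (!nrow(gs)) .stopf("unknown gradient region '%s'", reg)
      g <- gs$score[match(subjectIDs[pat], gs$subject_id)]
      if (anyNA(g))
        .stopf("gradient scores missing for some patients (region '%s')", reg)
      g <- as.numeric(scale(g))
      val[pat] <- mu + sd * (r * g + sqrt(1 - r^2) * noise[pat])
    } else {
      val[pat] <- mu + sd * noise[pat]
    }
    out[[sc]] <- val
  }
  out
}
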