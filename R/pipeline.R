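# End-to-end orchestration: simulate -> prep -> dFC -> gradients -> stats ->
# classify, with a YAML-serializable config, per-stage derived seeds, and a
# machine-readable JSON report listing every output file with its hash.

#' Default run configuration
#'
#' All module parameters with the study-design defaults; any part can be
#' overridden via the `...` (named nested lists are merged element-wise).
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param ... overrides, e.g. `cohort = list(P = 30)`.
#' @return nested list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1L, ...) {
  base <- list(
    seed = as.integer(seed),
    cohort = list(nPatients = 34, nControls = 32, T = 200, TR = 2, P = 90,
                  nStates = 4, stickiness = 0.9),
    prep = list(detrendOrder = 1, band = c(0.01, 0.08)),
    dfc = list(L = 50, s = 1, kRange = 2:8, k = "auto", nInit = 20,
               silhouetteSample = 1000),
    gradients = list(density = 0.10, alpha = 0.5, t = 0, nComponents = 10,
                     dispersionComponents = 2,
                     networks = list(
                       "default mode" = list(nVoxels = 150, shift = c(reg02 = 0.03, reg06 = -0.03)),
                       "somatomotor" = list(nVoxels = 150, shift = c(reg03 = 0.03)))),
    stats = list(q = 0.05, voxelP = 0.001, clusterP = 0.05, nPerm = 1000),
    classify = list(scheme = "loocv", topN = 12, edgeSource = "mean",
                    classifiers = c("svm-linear", "svm-rbf", "knn", "rf",
                                    "xgboost")))
  .mergeConfig(base, list(...))
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    # `networks` is replaced wholesale: merging would silently keep default
    # networks (and their planted shifts) alongside the user's set
    if (nm != "networks" && is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  class(base) <- "RunConfig"
  base
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys mirror [runConfig()]'s structure.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  y$seed <- NULL
  do.call(runConfig, c(list(seed = seed), y))
}

.writeCSV <- function(x, dir, name) {
  p <- file.path(dir, name)
  utils::write.csv(x, p, row.names = FALSE)
  p
}

.stageLog <- function(verbose, stage, ...) {
  if (verbose)
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste(..., collapse = " ")))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages: simulate the Markov-switching cohort and the per-network
#' connectivity manifolds; sliding-window dFC with state decomposition and
#' dynamics; per-subject gradients with template alignment, z-scoring and
#' dispersion; covariate-adjusted group statistics (FDR on edges,
#' permutation cluster correction on voxels); feature assembly and
#' multi-classifier cross-validation.  Every table is written under
#' `outDir` and listed in the JSON report with its MD5 hash; when ground
#' truth exists the report carries recovered-vs-true comparisons.
#'
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @param verbose log one line per stage.
#' @return the report, invisibly (also written to `report.json`).
#' @export
runPipeline <- function(config = runConfig(), outDir, verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  report <- list(config = unclass(config), seeds = list(master = seed))
  files <- character(0)
  stage <- "simulate"
  tryCatch({
    ## ---- simulate ----
    .stageLog(verbose, stage, sprintf("n=%d+%d T=%d P=%d",
              config$cohort$nPatients, config$cohort$nControls,
              config$cohort$T, config$cohort$P))
    report$seeds$simulate <- .deriveSeed(seed, 11L)
    cspec <- do.call(cohortSpec, c(config$cohort,
                                   list(seed = report$seeds$simulate,
                                        band = config$prep$band)))
    cohort <- simulateCohort(cspec)
    nets <- config$gradients$networks
    report$seeds$manifold <- .deriveSeed(seed, 12L)
    clin <- clinicalTable(cohort)
    groups <- clin$group
    manifolds <- lapply(seq_along(nets), function(ni) {
      ms <- gradientManifoldSpec(
        nVoxels = nets[[ni]]$nVoxels,
        groupShiftRegions = nets[[ni]]$shift %||% numeric(0),
        seed = .deriveSeed(report$seeds$manifold, ni))
      voxSeeds <- .seedBlock(.deriveSeed(report$seeds$manifold, 500L + ni),
                             length(groups))
      subs <- lapply(seq_along(groups), function(i)
        simulateNetworkVoxels(ms, groups[i], seed = voxSeeds[i]))
      list(spec = ms, subjects = subs)
    })
    names(manifolds) <- names(nets)

    ## ---- prep ----
    stage <- "prep"
    .stageLog(verbose, stage, sprintf("detrend order %d", config$prep$detrendOrder))
    subjects <- lapply(cohortSubjects(cohort), detrendTS,
                       order = config$prep$detrendOrder)

    ## ---- dfc ----
    stage <- "dfc"
    .stageLog(verbose, stage, sprintf("L=%d s=%d", config$dfc$L, config$dfc$s))
    report$seeds$dfc <- .deriveSeed(seed, 13L)
    stacks <- lapply(subjects, slidingWindowFC, L = config$dfc$L, s = config$dfc$s)
    nEdges <- ncol(zEdges(stacks[[1]]))
    edgeMaps <- list(
      variability = t(vapply(stacks, dfcVariability, numeric(nEdges))),
      mean = t(vapply(stacks, function(s) colMeans(zEdges(s)), numeric(nEdges))))
    for (nm in names(edgeMaps)) rownames(edgeMaps[[nm]]) <- clin$subject_id
    varMap <- edgeMaps$variability
    model <- if (identical(config$dfc$k, "auto")) {
      selectK(stacks, kRange = config$dfc$kRange, nInit = config$dfc$nInit,
              seed = report$seeds$dfc,
              silhouetteSample = config$dfc$silhouetteSample)
    } else {
      fitStates(stacks, k = config$dfc$k, nInit = config$dfc$nInit,
                seed = report$seeds$dfc)
    }
    dyn <- stateDynamics(model)
    report$dfc <- list(chosenK = model@k, SSE = model@SSE)
    if (nrow(selectionTable(model)))
      report$dfc$selection <- selectionTable(model)
    files <- c(files,
               .writeCSV(data.frame(subject = rownames(varMap), varMap,
                                    check.names = FALSE),
                         outDir, "dfc_variability.csv"),
               .writeCSV(dyn, outDir, "state_dynamics.csv"))
    jsonlite::write_json(
      list(k = model@k, centroids = centroids(model),
           selection = selectionTable(model)),
      file.path(outDir, "state_model.json"), digits = NA)
    files <- c(files, file.path(outDir, "state_model.json"))
    if (length(cohortTruth(cohort))) {
      # window-level truth = majority planted state within each window
      trueWin <- lapply(cohortTruth(cohort)$states, function(st) {
        starts <- (seq_len((length(st) - config$dfc$L) %/% config$dfc$s + 1L) - 1L) *
          config$dfc$s + 1L
        vapply(starts, function(s0) {
          tb <- tabulate(st[s0:(s0 + config$dfc$L - 1L)])
          which.max(tb)
        }, integer(1))
      })
      report$dfc$trueStates <- length(unique(unlist(lapply(
        cohortTruth(cohort)$states, unique))))
      report$dfc$windowAgreement <- .bestPermAgreement(
        unlist(stateLabels(model)), unlist(trueWin), model@k)
    }

    ## ---- gradients ----
    stage <- "gradients"
    .stageLog(verbose, stage, sprintf("%d network(s)", length(manifolds)))
    gcfg <- config$gradients
    gradResults <- lapply(names(manifolds), function(nw) {
      mf <- manifolds[[nw]]
      fcs <- lapply(mf$subjects, `[[`, "fc")
      tmpl <- groupTemplate(fcs, density = gcfg$density, alpha = gcfg$alpha,
                            t = gcfg$t, nComponents = gcfg$nComponents)
      aligned <- lapply(fcs, function(fc) {
        g <- computeGradients(fc, density = gcfg$density, alpha = gcfg$alpha,
                              t = gcfg$t, nComponents = gcfg$nComponents)
        zscoreGradients(smoothGradients(procrustesAlign(g, tmpl)))
      })
      g1 <- t(vapply(aligned, function(g) gradientComponents(g)[, 1],
                     numeric(mf$spec$nVoxels)))
      rownames(g1) <- clin$subject_id
      disp <- lapply(aligned, gradientDispersion,
                     regionLabels = mf$spec$regionOf,
                     nComponents = gcfg$dispersionComponents)
      list(network = nw, template = tmpl, aligned = aligned, g1 = g1,
           dispersion = disp, region = mf$spec$regionOf,
           latent = mf$spec$latent)
    })
    names(gradResults) <- names(manifolds)
    for (nw in names(gradResults)) {
      gr <- gradResults[[nw]]
      files <- c(files, .writeCSV(
        data.frame(subject = rep(clin$subject_id, each = ncol(gr$g1)),
                   voxel = rep(colnames(gr$g1) %||% seq_len(ncol(gr$g1)),
                               nrow(gr$g1)),
                   score = as.vector(t(gr$g1))),
        outDir, sprintf("gradients_%s.csv", gsub("\\s+", "_", nw))))
    }

    ## ---- stats ----
    stage <- "stats"
    report$seeds$stats <- .deriveSeed(seed, 14L)
    .stageLog(verbose, stage, sprintf("q=%g voxelP=%g nPerm=%d",
              config$stats$q, config$stats$voxelP, config$stats$nPerm))
    covars <- cbind(age = clin$age, sex = clin$sex)
    # both edge measures: SD (temporal variability, the headline) and mean z
    edgeStats <- lapply(edgeMaps, function(mp) {
      st <- adjustedGroupTest(mp, groups, covars)
      mask <- fdrCorrect(st$p, q = config$stats$q)
      st$p_fdr <- attr(mask, "p_fdr")
      st$significant <- as.logical(mask)
      st
    })
    for (nm in names(edgeStats))
      files <- c(files, .writeCSV(edgeStats[[nm]], outDir,
                                  sprintf("edge_stats_%s.csv", nm)))
    clusterTables <- lapply(names(gradResults), function(nw) {
      gr <- gradResults[[nw]]
      ct <- clusterCorrectPermutation(
        gr$g1, groups, gr$region, covariates = covars,
        voxelP = config$stats$voxelP, clusterP = config$stats$clusterP,
        nPerm = config$stats$nPerm,
        seed = .deriveSeed(report$seeds$stats, match(nw, names(gradResults))))
      if (nrow(ct)) ct$network <- nw
      ct
    })
    names(clusterTables) <- names(gradResults)
    allClusters <- do.call(rbind, clusterTables[vapply(clusterTables, nrow,
                                                       integer(1)) > 0])
    if (is.null(allClusters)) allClusters <- clusterTables[[1]]
    files <- c(files, .writeCSV(allClusters, outDir, "gradient_clusters.csv"))
    # dynamics and dispersion group tests
    dynCols <- setdiff(names(dyn), "subject")
    # dwell of an unvisited state is NA: listwise exclusion per state's test
    dynStats <- do.call(rbind, lapply(dynCols, function(cl) {
      v <- dyn[[cl]]
      ok <- !is.na(v)
      if (min(table(groups[ok])) < 3) return(NULL)
      st <- adjustedGroupTest(matrix(v[ok], ncol = 1,
                                     dimnames = list(NULL, cl)),
                              groups[ok], covars[ok, , drop = FALSE])
      st$n <- sum(ok)
      st
    }))
    files <- c(files, .writeCSV(dynStats, outDir, "dynamics_stats.csv"))
    report$stats <- list(
      nSignificantEdges = lapply(edgeStats, function(st) sum(st$significant)),
      significantEdges = lapply(edgeStats, function(st)
        st$feature[st$significant]),
      significantClusters = if (nrow(allClusters))
        allClusters[allClusters$significant, c("network", "region", "start",
                                               "end", "size", "cluster_p")]
      else list())
    if (length(cohortTruth(cohort))) {
      eff <- cohortTruth(cohort)$effectEdges
      effNames <- .edgeNames(cspec$regionIDs)[
        match(paste(pmin(eff$i, eff$j), pmax(eff$i, eff$j)),
              apply(.edgePairs(cspec$P), 1, paste, collapse = " "))]
      report$stats$plantedEdges <- effNames
      # a planted covariance shift manifests in the mean-z map
      report$stats$plantedEdgeRecovered <-
        effNames %in% edgeStats$mean$feature[edgeStats$mean$significant]
      planted <- unlist(lapply(names(nets), function(nw) {
        sh <- nets[[nw]]$shift
        if (length(sh)) paste(nw, names(sh), sep = ":") else character(0)
      }))
      report$stats$plantedGradientRegions <- planted
      if (length(planted)) {
        sigRegs <- if (nrow(allClusters))
          paste(allClusters$network[allClusters$significant],
                allClusters$region[allClusters$significant], sep = ":")
        else character(0)
        report$stats$plantedGradientRecovered <- planted %in% sigRegs
      }
    }
    # clinical correlations: patients only, gradient-1 region means
    pat <- groups == "patient"
    regMeans <- do.call(cbind, lapply(names(gradResults), function(nw) {
      gr <- gradResults[[nw]]
      m <- vapply(unique(gr$region), function(rg)
        rowMeans(gr$g1[, gr$region == rg, drop = FALSE]), numeric(nrow(gr$g1)))
      colnames(m) <- paste(gsub("\\s+", "_", nw), unique(gr$region), sep = ":")
      m
    }))
    clinVars <- intersect(c("age", "duration_years", "verbal_comprehension",
                            "perceptual_processing", "working_memory",
                            "processing_speed", "full_scale"), names(clin))
    corrs <- clinicalCorrelations(regMeans[pat, , drop = FALSE],
                                  clin[pat, clinVars, drop = FALSE])
    files <- c(files, .writeCSV(corrs, outDir, "clinical_correlations.csv"))

    ## ---- classify ----
    stage <- "classify"
    report$seeds$classify <- .deriveSeed(seed, 15L)
    .stageLog(verbose, stage, paste(config$classify$classifiers, collapse = ", "))
    primary <- gradResults[[1]]
    edgeSource <- config$classify$edgeSource
    feats <- assembleFeatures(primary$g1, clusterTables[[1]],
                              edgeMaps[[edgeSource]], edgeStats[[edgeSource]],
                              topN = config$classify$topN)
    rownames(feats$x) <- clin$subject_id
    cvs <- lapply(config$classify$classifiers, function(cl)
      crossValidate(feats$x, groups, classifier = cl,
                    scheme = config$classify$scheme,
                    seed = report$seeds$classify))
    names(cvs) <- config$classify$classifiers
    metricsTab <- do.call(rbind, lapply(names(cvs), function(cl)
      data.frame(classifier = cl, t(cvMetrics(cvs[[cl]])))))
    files <- c(files, .writeCSV(metricsTab, outDir, "cv_metrics.csv"),
               .writeCSV(feats$provenance, outDir, "feature_provenance.csv"),
               .writeCSV(rankFeatures(feats$x, groups), outDir,
                         "feature_ranking.csv"))
    report$classification <- list(
      scheme = config$classify$scheme,
      nFeatures = ncol(feats$x),
      metrics = metricsTab)
  }, error = function(e) {
    .stopf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
           stage, conditionMessage(e), outDir)
  })
  report$files <- data.frame(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(report)
}

# best-permutation label agreement between two labelings with <= k states
# (exhaustive over permutations of 1..k; k is small)
.bestPermAgreement <- function(est, truth, k) {
  perms <- .permutations(seq_len(k))
  best <- 0
  for (p in perms) best <- max(best, mean(p[est] == truth))
  best
}

.permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.permutations(v[-i]), function(p) c(v[i], p)))
  out
}
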