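# Per-network functional-gradient pipeline: voxel-to-parcel connectivity,
# row-density sparsification, cosine affinity, diffusion-map embedding,
# group-template Procrustes alignment, z-scoring, and gradient dispersion.

#' Voxel-by-parcel connectivity matrix
#'
#' Pearson correlation between each voxel's series and each parcel's mean
#' series, clipped to +/-(1 - 1e-7) and Fisher-z transformed.
#'
#' @param voxelTS numeric T x nVoxels matrix.
#' @param parcelTS numeric T x nParcels matrix (parcel mean series).
#' @return nVoxels x nParcels Fisher-z matrix.
#' @export
buildNetworkFC <- function(voxelTS, parcelTS) {
  voxelTS <- as.matrix(voxelTS); parcelTS <- as.matrix(parcelTS)
  if (nrow(voxelTS) != nrow(parcelTS))
    .stopf("voxel and parcel series must share the same number of time points")
  sds <- apply(voxelTS, 2, stats::sd)
  r <- matrix(0, ncol(voxelTS), ncol(parcelTS))
  ok <- sds > 0
  if (any(!ok))
    .warnf("%d constant voxel series; their rows were set to 0", sum(!ok))
  if (any(ok))
    r[ok, ] <- stats::cor(voxelTS[, ok, drop = FALSE], parcelTS)
  fc <- .fisherZ(r)
  rownames(fc) <- colnames(voxelTS)
  colnames(fc) <- colnames(parcelTS)
  fc
}

#' Row-density sparsification
#'
#' Per row, retains the `ceiling(density * ncol)` largest values and zeroes
#' the rest; ties at the threshold are broken toward the lower column index.
#'
#' @param fc numeric matrix.
#' @param density fraction of entries retained per row, in (0, 1].
#' @return matrix of the same shape.
#' @export
sparsifyRows <- function(fc, density = 0.10) {
  if (density <= 0 || density > 1) .stopf("density must lie in (0, 1]")
  m <- ceiling(density * ncol(fc))
  if (m == ncol(fc)) return(fc)
  out <- matrix(0, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  for (i in seq_len(nrow(fc))) {
    keep <- order(fc[i, ], decreasing = TRUE)[seq_len(m)]  # stable: lower index wins ties
    out[i, keep] <- fc[i, keep]
  }
  out
}

#' Cosine similarity of sparsified connectivity profiles
#'
#' `A[i,j] = <row_i, row_j> / (|row_i| |row_j|)`, diagonal forced to 1.
#'
#' @param sfc sparsified connectivity matrix (rows = voxels).
#' @return symmetric nVoxels x nVoxels similarity matrix.
#' @export
cosineAffinity <- function(sfc) {
  nrm <- sqrt(rowSums(sfc^2))
  zero <- which(nrm == 0)
  if (length(zero))
    .stopf("all-zero connectivity profile for voxel(s): %s (constant series upstream?)",
           paste(if (is.null(rownames(sfc))) zero else rownames(sfc)[zero],
                 collapse = ", "))
  A <- tcrossprod(sfc / nrm)
  diag(A) <- 1
  A
}

#' Diffusion-map embedding
#'
#' Degree-normalizes the affinity `W' = D^-alpha W D^-alpha`, forms the
#' row-stochastic diffusion operator, and returns its leading nontrivial
#' right eigenvectors ordered by non-increasing eigenvalue (the trivial
#' constant eigenvector at eigenvalue 1 is dropped).  With `t = 0`
#' component i is scaled by `lambda_i / (1 - lambda_i)` (the automatic
#' diffusion-time convention); with `t > 0` by `lambda_i^t`.  Negative
#' affinities are clipped to 0 before normalization (the operator requires
#' non-negative weights); the clip rate is reported.
#'
#' @param A symmetric affinity matrix.
#' @param alpha anisotropic diffusion exponent (0.5 default).
#' @param t diffusion time (0 default).
#' @param nComponents components to return.
#' @return a [GradientSet-class].
#' @export
diffusionEmbedding <- function(A, alpha = 0.5, t = 0, nComponents = 10L) {
  if (!isSymmetric(unname(A), tol = 1e-8)) .stopf("affinity must be symmetric")
  A <- (A + t(A)) / 2
  neg <- A < 0
  if (any(neg)) {
    message(sprintf("clipping %.2f%% negative affinities to 0",
                    100 * mean(neg)))
    A[neg] <- 0
  }
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    .stopf("affinity graph is disconnected (component sizes: %s)",
           paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  d <- rowSums(A)
  Wn <- A / outer(d^alpha, d^alpha)
  d1 <- rowSums(Wn)
  S <- Wn / outer(sqrt(d1), sqrt(d1))   # symmetric conjugate of the operator
  e <- eigen(S, symmetric = TRUE)
  lambda <- e$values
  psi <- e$vectors / sqrt(d1)           # right eigenvectors of D1^-1 W'
  keep <- 2:(nComponents + 1L)
  if (max(keep) > length(lambda)) .stopf("nComponents too large for this graph")
  lam <- lambda[keep]
  comps <- psi[, keep, drop = FALSE]
  scaleFac <- if (t == 0) lam / (1 - lam) else lam^t
  comps <- sweep(comps, 2, scaleFac, "*")
  # permutation-invariant sign convention: largest-magnitude entry positive
  for (j in seq_len(ncol(comps))) {
    m <- which.max(abs(comps[, j]))
    if (comps[m, j] < 0) comps[, j] <- -comps[, j]
  }
  rownames(comps) <- rownames(A)
  colnames(comps) <- paste0("G", seq_len(ncol(comps)))
  new("GradientSet", components = comps, eigenvalues = lam,
      aligned = FALSE, zscored = FALSE, alpha = alpha, t = t)
}

#' Full per-subject gradient computation
#'
#' Convenience chain: [sparsifyRows()] -> [cosineAffinity()] ->
#' [diffusionEmbedding()].
#'
#' @param fc voxel-by-parcel Fisher-z matrix.
#' @inheritParams diffusionEmbedding
#' @param density row density for sparsification.
#' @return a [GradientSet-class].
#' @export
computeGradients <- function(fc, density = 0.10, alpha = 0.5, t = 0,
                             nComponents = 10L) {
  diffusionEmbedding(cosineAffinity(sparsifyRows(fc, density)),
                     alpha = alpha, t = t, nComponents = nComponents)
}

#' Group-level gradient template
#'
#' Entry-wise average of the subjects' voxel-by-parcel connectivity
#' matrices, then the standard sparsify -> affinity -> embed chain.
#'
#' @param fcList list (>= 2) of equally shaped voxel-by-parcel matrices.
#' @inheritParams computeGradients
#' @return a [GradientSet-class].
#' @export
groupTemplate <- function(fcList, density = 0.10, alpha = 0.5, t = 0,
                          nComponents = 10L) {
  if (length(fcList) < 2L) .stopf("need at least 2 subjects for a template")
  dims <- vapply(fcList, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    .stopf("subject FC matrices differ in shape")
  avg <- Reduce(`+`, fcList) / length(fcList)
  computeGradients(avg, density, alpha, t, nComponents)
}

#' Procrustes alignment to a template
#'
#' Orthogonal transform (rotation/reflection, no scaling, after column
#' centering) minimizing the Frobenius distance of the individual's
#' components to the template's; the template's column means are restored
#' afterwards.  If the cross-product is rank deficient the alignment falls
#' back to per-component sign matching (reported).  After alignment each
#' component's sign is fixed so its correlation with the template component
#' is non-negative.
#'
#' @param individual a [GradientSet-class] (or matrix).
#' @param template a [GradientSet-class] (or matrix) of matching shape.
#' @return the aligned [GradientSet-class]; attribute `rotation` carries the
#'   orthogonal transform, `disparity` the residual Frobenius distance.
#' @export
procrustesAlign <- function(individual, template) {
  X <- if (is(individual, "GradientSet")) gradientComponents(individual) else individual
  Tm <- if (is(template, "GradientSet")) gradientComponents(template) else template
  if (!all(dim(X) == dim(Tm))) .stopf("shapes of individual and template differ")
  mx <- colMeans(X); mt <- colMeans(Tm)
  Xc <- sweep(X, 2, mx); Tc <- sweep(Tm, 2, mt)
  M <- crossprod(Xc, Tc)
  sv <- svd(M)
  tol <- max(dim(M)) * max(sv$d, 0) * .Machine$double.eps
  if (min(sv$d) <= tol) {
    message("rank-deficient cross-product; falling back to per-component sign matching")
    Q <- diag(sign(diag(M) + (diag(M) == 0)), ncol(X))
  } else {
    Q <- sv$u %*% t(sv$v)
  }
  aligned <- Xc %*% Q
  # sign convention vs template
  for (j in seq_len(ncol(aligned))) {
    if (stats::sd(aligned[, j]) > 0 && stats::sd(Tc[, j]) > 0 &&
        stats::cor(aligned[, j], Tc[, j]) < 0) {
      aligned[, j] <- -aligned[, j]
      Q[, j] <- -Q[, j]
    }
  }
  aligned <- sweep(aligned, 2, mt, "+")
  dimnames(aligned) <- dimnames(X)
  out <- if (is(individual, "GradientSet")) {
    initialize(individual, components = aligned, aligned = TRUE)
  } else {
    new("GradientSet", components = aligned,
        eigenvalues = rep(NA_real_, ncol(aligned)), aligned = TRUE,
        zscored = FALSE, alpha = NA_real_, t = NA_real_)
  }
  attr(out, "rotation") <- Q
  attr(out, "disparity") <- sqrt(sum((sweep(aligned, 2, mt) - Tc)^2))
  out
}

#' Standardize gradient components to z-scores
#'
#' Per component: mean 0, SD 1 across voxels.
#'
#' @param gset an aligned [GradientSet-class].
#' @return the z-scored [GradientSet-class].
#' @export
zscoreGradients <- function(gset) {
  stopifnot(is(gset, "GradientSet"))
  G <- gradientComponents(gset)
  sds <- apply(G, 2, stats::sd)
  if (any(sds == 0)) .stopf("component(s) %s have zero variance",
                            paste(which(sds == 0), collapse = ", "))
  Z <- scale(G)
  attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL
  initialize(gset, components = `dimnames<-`(unclass(Z), dimnames(G)),
             zscored = TRUE)
}

#' Spatial-smoothing hook
#'
#' The abstract voxels of this package carry no geometry, so no smoothing
#' kernel is defined; this no-op hook marks the place where surface- or
#' volume-based smoothing would act on real data.
#'
#' @param gset a [GradientSet-class].
#' @return `gset`, unchanged.
#' @export
smoothGradients <- function(gset) gset

#' Gradient dispersion
#'
#' Region centroids are computed in the retained gradient space (first
#' `nComponents` components); the headline metric is the pairwise Euclidean
#' distance between centroids, with within-region dispersion (mean distance
#' of a region's voxels to their centroid) computed alongside.
#'
#' @param gset a [GradientSet-class].
#' @param regionLabels character/factor label per voxel.
#' @param nComponents dimensionality of the dispersion space (default 2).
#' @return list with `between` (data.frame `region_i`, `region_j`,
#'   `distance`) and `within` (data.frame `region`, `dispersion`, `nVoxels`).
#' @export
gradientDispersion <- function(gset, regionLabels, nComponents = 2L) {
  stopifnot(is(gset, "GradientSet"))
  G <- gradientComponents(gset)
  if (length(regionLabels) != nrow(G))
    .stopf("one region label per voxel required")
  nComponents <- min(nComponents, ncol(G))
  G <- G[, seq_len(nComponents), drop = FALSE]
  declared <- if (is.factor(regionLabels)) levels(regionLabels) else
    unique(as.character(regionLabels))
  regionLabels <- as.character(regionLabels)
  regs <- intersect(declared, regionLabels)
  counts <- table(regionLabels)[regs]
  empty <- setdiff(declared, regionLabels)
  if (length(empty)) .warnf("excluding empty region(s): %s",
                            paste(empty, collapse = ", "))
  if (length(regs) < 2L) .stopf("need at least 2 non-empty regions")
  cent <- t(vapply(regs, function(rg)
    colMeans(G[regionLabels == rg, , drop = FALSE]), numeric(nComponents)))
  within <- vapply(regs, function(rg) {
    sub <- G[regionLabels == rg, , drop = FALSE]
    mu <- colMeans(sub)
    mean(sqrt(rowSums(sweep(sub, 2, mu)^2)))
  }, numeric(1))
  pairs <- utils::combn(seq_along(regs), 2)
  between <- data.frame(
    region_i = regs[pairs[1, ]],
    region_j = regs[pairs[2, ]],
    distance = apply(pairs, 2, function(p)
      sqrt(sum((cent[p[1], ] - cent[p[2], ])^2))))
  list(between = between,
       within = data.frame(region = regs, dispersion = within,
                           nVoxels = as.integer(counts)))
}
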