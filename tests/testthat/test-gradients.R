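# Voxel-parcel connectivity, sparsification, affinity, diffusion embedding,
# Procrustes alignment, z-scoring, dispersion.

test_that("voxel-parcel connectivity has the right shape and self-correlation", {
  set.seed(1)
  Tn <- 100
  parcels <- matrix(rnorm(Tn * 20), Tn, 20,
                    dimnames = list(NULL, sprintf("p%02d", 1:20)))
  voxels <- cbind(v1 = parcels[, 5], v2 = rnorm(Tn))
  fc <- buildNetworkFC(voxels, parcels)
  expect_equal(dim(fc), c(2, 20))
  expect_equal(fc["v1", "p05"], atanh(1 - 1e-7))
  expect_equal(unname(which.max(fc["v1", ])), 5)
})

test_that("independent noise gives near-zero rows; constant voxels are zeroed", {
  set.seed(2)
  parcels <- matrix(rnorm(200 * 400), 200, 400)
  voxels <- matrix(rnorm(200 * 3), 200, 3)
  fc <- buildNetworkFC(voxels, parcels)
  expect_lt(max(abs(rowMeans(fc))), 0.05)
  voxels[, 2] <- 1
  expect_warning(fc2 <- buildNetworkFC(voxels, parcels), "constant")
  expect_true(all(fc2[2, ] == 0))
})

test_that("row sparsification keeps the densest entries with a stable tie rule", {
  set.seed(3)
  M <- matrix(rnorm(5 * 400), 5, 400)
  S <- sparsifyRows(M, 0.10)
  expect_true(all(rowSums(S != 0) == 40))
  # retained entries are each row's largest
  for (i in 1:5)
    expect_setequal(which(S[i, ] != 0), order(M[i, ], decreasing = TRUE)[1:40])
  expect_identical(sparsifyRows(M, 1), M)
  tie <- matrix(1, 1, 400)
  expect_equal(which(sparsifyRows(tie, 0.10)[1, ] != 0), 1:40)
})

test_that("cosine affinity matches a brute-force double loop", {
  set.seed(4)
  S <- sparsifyRows(matrix(rnorm(100 * 400), 100, 400), 0.10)
  A <- cosineAffinity(S)
  brute <- matrix(0, 100, 100)
  for (i in 1:100) for (j in 1:100)
    brute[i, j] <- sum(S[i, ] * S[j, ]) /
      (sqrt(sum(S[i, ]^2)) * sqrt(sum(S[j, ]^2)))
  diag(brute) <- 1
  expect_equal(A, brute, tolerance = 1e-10)
})

test_that("cosine affinity handles parallel, orthogonal and zero rows", {
  S <- rbind(c(1, 2, 0, 0), c(2, 4, 0, 0), c(0, 0, 3, 1))
  A <- cosineAffinity(S)
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], 0)
  expect_error(cosineAffinity(rbind(c(1, 1), c(0, 0))), "all-zero")
})

test_that("ring-graph embedding yields the circulant sinusoid", {
  n <- 64
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, (i %% n) + 1] <- 1
    A[(i %% n) + 1, i] <- 1
  }
  g <- diffusionEmbedding(A, alpha = 0.5, t = 0, nComponents = 4)
  c1 <- gradientComponents(g)[, 1]
  th <- 2 * pi * (seq_len(n) - 1) / n
  # cosine similarity to the best-phase unit sinusoid of the fundamental
  proj <- sqrt(sum(c1 * cos(th))^2 + sum(c1 * sin(th))^2)
  cossim <- proj / (sqrt(sum(c1^2)) * sqrt(n / 2))
  expect_gte(cossim, 0.99)
  ev <- eigenvalues(g)
  expect_true(all(ev >= -1 - 1e-8 & ev <= 1 + 1e-8))
  expect_true(all(diff(ev) <= 1e-8))
})

test_that("disconnected affinity graphs are rejected with component sizes", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 0.5; A[4:6, 4:6] <- 0.5
  diag(A) <- 1
  expect_error(diffusionEmbedding(A), "disconnected.*3, 3")
})

test_that("the planted manifold's latent coordinate is recovered by gradient 1", {
  ms <- gradientManifoldSpec(nVoxels = 150, nParcels = 300, seed = 5)
  sv <- simulateNetworkVoxels(ms, "control", seed = 7)
  g <- computeGradients(sv$fc, nComponents = 5)
  rho <- cor(gradientComponents(g)[, 1], sv$latent, method = "spearman")
  expect_gte(abs(rho), 0.9)
})

test_that("embedding is equivariant under voxel permutation", {
  ms <- gradientManifoldSpec(nVoxels = 80, nParcels = 150, seed = 6)
  sv <- simulateNetworkVoxels(ms, "control", seed = 8)
  A <- cosineAffinity(sparsifyRows(sv$fc, 0.10))
  g <- diffusionEmbedding(A, nComponents = 3)
  set.seed(1); perm <- sample(80)
  gp <- diffusionEmbedding(A[perm, perm], nComponents = 3)
  expect_equal(unname(gradientComponents(gp)),
               unname(gradientComponents(g)[perm, ]), tolerance = 1e-6)
})

test_that("the group template reduces to the individual case and is order-invariant", {
  ms <- gradientManifoldSpec(nVoxels = 70, nParcels = 120, seed = 9)
  fcs <- lapply(1:4, function(i) simulateNetworkVoxels(ms, "control",
                                                       seed = 20 + i)$fc)
  same <- groupTemplate(list(fcs[[1]], fcs[[1]], fcs[[1]]), nComponents = 3)
  ind <- computeGradients(fcs[[1]], nComponents = 3)
  expect_equal(gradientComponents(same), gradientComponents(ind),
               tolerance = 1e-10)
  t1 <- groupTemplate(fcs, nComponents = 3)
  t2 <- groupTemplate(rev(fcs), nComponents = 3)
  expect_equal(gradientComponents(t1), gradientComponents(t2),
               tolerance = 1e-10)
  # two-subject template embeds the midpoint matrix
  tm <- groupTemplate(fcs[1:2], nComponents = 3)
  mid <- computeGradients((fcs[[1]] + fcs[[2]]) / 2, nComponents = 3)
  expect_equal(gradientComponents(tm), gradientComponents(mid),
               tolerance = 1e-10)
  expect_error(groupTemplate(fcs[1]), "at least 2")
  expect_error(groupTemplate(list(fcs[[1]], fcs[[2]][1:10, ])), "shape")
})

test_that("Procrustes alignment is exact for identity, reflection and rotation", {
  set.seed(10)
  Tm <- matrix(rnorm(60 * 4), 60, 4)
  self <- procrustesAlign(Tm, Tm)
  expect_equal(attr(self, "disparity"), 0, tolerance = 1e-10)
  expect_equal(attr(self, "rotation"), diag(4), tolerance = 1e-8)
  flip <- Tm %*% diag(c(1, -1, 1, -1))
  expect_equal(gradientComponents(procrustesAlign(flip, Tm)), Tm,
               tolerance = 1e-8, ignore_attr = TRUE)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  rot <- sweep(sweep(Tm, 2, colMeans(Tm)) %*% Q, 2, colMeans(Tm), "+")
  out <- procrustesAlign(rot, Tm)
  expect_lt(attr(out, "disparity"), 1e-8)
  expect_equal(attr(out, "rotation") %*% Q, diag(4) + 0 * Q, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("alignment never increases the Frobenius distance to the template", {
  set.seed(11)
  for (i in 1:20) {
    Tm <- matrix(rnorm(40 * 3), 40, 3)
    X <- matrix(rnorm(40 * 3), 40, 3)
    out <- gradientComponents(procrustesAlign(X, Tm))
    expect_lte(sqrt(sum((out - Tm)^2)), sqrt(sum((X - Tm)^2)) + 1e-10)
  }
})

test_that("alignment agrees with an independent Procrustes implementation", {
  set.seed(12)
  Tm <- matrix(rnorm(50 * 3), 50, 3)
  X <- matrix(rnorm(50 * 3), 50, 3)
  ours <- gradientComponents(procrustesAlign(X, Tm))
  oursCentered <- sweep(ours, 2, colMeans(Tm))  # alignment restores template means
  ref <- vegan::procrustes(Tm, X, scale = FALSE)
  expect_equal(unname(oursCentered), unname(ref$Yrot), tolerance = 1e-8)
})

test_that("z-scoring standardizes, is affine-invariant, and rejects constants", {
  set.seed(13)
  g <- computeGradients(simulateNetworkVoxels(
    gradientManifoldSpec(nVoxels = 60, nParcels = 100, seed = 1),
    "control", seed = 2)$fc, nComponents = 3)
  z <- zscoreGradients(g)
  G <- gradientComponents(z)
  expect_equal(unname(colMeans(G)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(G, 2, sd)), rep(1, 3), tolerance = 1e-12)
  g2 <- initialize(g, components = 2.5 * gradientComponents(g) + 7)
  expect_equal(gradientComponents(zscoreGradients(g2)), G, tolerance = 1e-10)
  gconst <- new("GradientSet",
                components = cbind(gradientComponents(g)[, 1], 3),
                eigenvalues = c(0.5, 0.4), aligned = TRUE, zscored = FALSE,
                alpha = 0.5, t = 0)
  expect_error(zscoreGradients(gconst), "zero variance")
})

test_that("dispersion distances match geometry and a brute-force recount", {
  G <- rbind(c(0, 0), c(0, 0), c(3, 4), c(3, 4))
  gs <- new("GradientSet", components = G, eigenvalues = c(0.5, 0.3),
            aligned = TRUE, zscored = TRUE, alpha = 0.5, t = 0)
  d <- gradientDispersion(gs, c("a", "a", "b", "b"))
  expect_equal(d$between$distance, 5)
  expect_equal(d$within$dispersion, c(0, 0))
  # identical centroids -> zero distance
  d0 <- gradientDispersion(gs, c("a", "b", "a", "b"))
  expect_equal(d0$between$distance, 0)
  # random labels vs brute force
  set.seed(14)
  G <- matrix(rnorm(60 * 2), 60, 2)
  gs <- new("GradientSet", components = G, eigenvalues = c(0.5, 0.3),
            aligned = TRUE, zscored = TRUE, alpha = 0.5, t = 0)
  lab <- sample(letters[1:4], 60, replace = TRUE)
  d <- gradientDispersion(gs, lab)
  for (r in seq_len(nrow(d$between))) {
    ci <- colMeans(G[lab == d$between$region_i[r], , drop = FALSE])
    cj <- colMeans(G[lab == d$between$region_j[r], , drop = FALSE])
    expect_equal(d$between$distance[r], sqrt(sum((ci - cj)^2)),
                 tolerance = 1e-10)
  }
  # empty declared region is excluded with a warning
  expect_warning(
    gradientDispersion(gs, factor(lab, levels = c(letters[1:4], "zz"))),
    "empty region")
})
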