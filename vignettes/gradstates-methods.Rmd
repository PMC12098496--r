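---
title: "Dynamic connectivity states and functional gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states and functional gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gradstates` implements a two-track analysis of two-group resting-state BOLD
cohorts — a pediatric focal-epilepsy patient group versus healthy controls in
the motivating application, but nothing in the code is specific to that
label.  Track one decomposes time-varying functional connectivity into
recurring whole-brain *states*; track two characterizes the low-dimensional
*functional gradient* organization of individual brain networks.  Both feed
covariate-adjusted group statistics and a cross-validated classification
stage.  Because no patient data ship with the package, a synthetic cohort
generator with known ground truth is a first-class module: every downstream
stage is validated against quantities the generator plants.

The package operates on parcel- or voxel-level time series that have already
been through standard image-space preprocessing (slice-timing, realignment,
normalization, smoothing, nuisance regression).  Those steps belong to the
established MRI tools; `gradstates` owns only detrending and band-pass
filtering, the two conditioning steps its statistics depend on.

# Dynamic connectivity states

For each subject the T x P series is cut into sliding windows of `L` volumes
advanced by `s` volumes, giving `floor((T - L)/s) + 1` windows — with the
default T = 200, L = 50, s = 1, exactly 151 windows.  Within each window
the pairwise Pearson correlations are clipped to ±(1 − 1e−7) and
variance-stabilized with Fisher's z = atanh(r).  The per-edge standard
deviation of z across windows is the *variability map*; the per-edge mean is
kept alongside, because a group difference in coupling strength appears in
the mean while a difference in coupling stability appears in the SD, and the
two maps answer different questions.

Window vectors (strict upper triangle, row-major, P(P−1)/2 edges) are pooled
across subjects and clustered with Lloyd's k-means: k-means++ seeding, best
of `nInit = 20` restarts by SSE, centroid update as the mean of assigned
vectors, convergence when assignments stop changing (cap 300 iterations).
An empty cluster is re-seeded at the point farthest from its centroid.  The
inner loop is compiled (Elkan's triangle-inequality bounds with incremental
centroid sums); it produces exactly the Lloyd fixed points — a test pins its
output against `stats::kmeans` started from identical centers — but runs an
order of magnitude faster on the ~10^4 x 435 pooled-window problems the
default cohort produces, which is what keeps the 20-seed model-selection
experiments tractable on one CPU.

The number of states is chosen from the SSE curve over k = 2..8: both axes
are normalized to [0, 1] and the elbow is the k with maximum perpendicular
distance to the chord joining the curve's endpoints.  The mean silhouette
width and the Calinski–Harabasz index are computed for every candidate and
reported alongside; on disagreement the elbow wins and the disagreement is
logged.  If the SSE curve is exactly linear there is no elbow and the
silhouette argmax is used.  The silhouette needs an O(n²) distance matrix,
so it is evaluated on a seeded subsample of at most `silhouetteSample = 1000`
windows; SSE and CH always use all windows.

Per-subject state dynamics follow directly from the label sequences:
fractional occupancy, number of transitions, transition frequency
(transitions per available switch, W − 1), and mean dwell time as the mean
length of maximal runs.  The dwell time of a state a subject never visits is
undefined; it is reported as NA and excluded listwise from that state's
group test.

# Functional gradients

For one network at a time, each voxel's time series is correlated with the
mean series of each of 400 cortical parcels, Fisher-z transformed, and the
top 10% of each row retained (ties broken toward the lower column index so
results are deterministic).  Cosine similarity between sparsified rows gives
the voxel-by-voxel affinity matrix.  Negative similarities — possible when
negative z values survive the row threshold — are clipped to zero before
normalization, because the diffusion operator requires non-negative weights;
the clip rate is reported.

The affinity W is degree-normalized as W' = D^−α W D^−α with α = 0.5, the
row-stochastic operator P = D'^−1 W' is formed, and its leading right
eigenvectors are extracted through the symmetric conjugate
S = D'^−1/2 W' D'^−1/2 (so a symmetric eigensolver applies).  The constant
eigenvector at eigenvalue 1 is dropped.  With diffusion time t = 0 each
component i is scaled by λᵢ/(1 − λᵢ) — the "automatic" diffusion-time
convention of the gradient toolchain this pipeline follows; t > 0 scales by
λᵢᵗ instead.  Components are returned in non-increasing eigenvalue order,
with a permutation-invariant sign convention (largest-magnitude entry
positive).  A disconnected affinity graph is an error that reports the
component sizes rather than silently embedding one piece.

The group template is the embedding of the entry-wise average of all
subjects' network FC matrices.  Individual gradients are aligned to the
template with orthogonal Procrustes — column-center both, rotate by UVᵀ from
the SVD of the cross-product, no scaling — and each component's sign is then
fixed so its correlation with the template component is non-negative.
Scaling is deliberately omitted: the subsequent z-scoring (per component:
mean 0, SD 1 across voxels) removes scale anyway, and a scale-free transform
keeps the eigenvalue information interpretable.  The smoothing step some
gradient workflows apply to aligned components has no defined kernel for abstract voxels
without geometry, so `smoothGradients()` is an explicit no-op hook where a
surface-based smoother would act on real data.

Gradient dispersion is computed in the space of the first 2 aligned
components (the primary gradients carry the interpretable signal; 2 is a
package default, not an empirical claim): region centroids are the mean
coordinates of each region's voxels, the headline metric is the pairwise
Euclidean distance between centroids, and within-region dispersion (mean
distance of voxels to their centroid) is computed alongside.  Both variants
exist because the field's phrasing is ambiguous between them; the
between-region distance is the quoted definition, so it leads.

# Group statistics

Mass-univariate comparisons fit `value ~ intercept + group + age + sex` per
feature (one QR decomposition shared across features) and report the group
coefficient's t with n − 4 degrees of freedom; group is coded 0/1 with
patients as 1, so positive t means patients above controls.  Without
covariates this reduces exactly to the pooled two-sample t — a property the
tests verify to 1e−10 against the textbook formula.  Edge- and metric-level
families are corrected with Benjamini–Hochberg FDR.

Voxel-level gradient maps are corrected with a permutation cluster-extent
procedure: supra-threshold voxels at two-sided p < 0.001, clusters formed
over a chain adjacency within each region (synthetic voxels have an order,
not a 3-D lattice), and the null distribution of the maximal cluster size
built from group-label permutations.  The cluster p is the add-one
proportion (b + 1)/(nPerm + 1), which is the standard exact form and keeps
p in (0, 1]; `nPerm` below 1/clusterP cannot resolve the threshold and is
rejected.  A parametric random-field correction is out of scope by design:
synthetic voxels carry no smoothness or geometry for its assumptions, while
permutation is exact under exchangeability.

Clinical association uses plain Pearson correlation (r, R² = r², two-sided
p from the t transform with n − 2 df), patients only by default, with
zero-variance or undersized pairs flagged and excluded.  For the demographic
table both pooled- and Welch-variance two-sample tests are available through
`stats::t.test`'s `var.equal` switch; the package asserts neither as
canonical.

# Classification

The feature table combines mean aligned gradient scores within selected
voxel clusters ("FG:" features) and dynamic-connectivity values at selected
edges ("dFC:" features) — significant candidates first, top-|t| fallback —
with a default of 12 + 12 = 24 features.  Five classifiers are evaluated:
linear SVM (C = 1), RBF SVM (bandwidth 1/(n_features · var), the library
default on standardized inputs), k-nearest neighbors (k = 5), random forest
(100 trees), and gradient-boosted trees (depth 3, 100 rounds, learning rate
0.1).  None of these hyperparameters are tuned; the package deliberately
ships fixed, conventional values because hyperparameter search is outside
its scope.

Under leave-one-out CV there are exactly n folds; 5-fold CV is stratified
and seeded.  Standardization parameters are estimated on training folds only
and recorded per fold, so leakage is auditable after the fact.  Decision
scores are pooled across folds into a single ROC (per-fold ROCs are
undefined at test size 1); the trapezoidal AUC of that pooled curve equals
the Mann–Whitney rank statistic, which the tests assert to 1e−10.  Accuracy,
precision, sensitivity and specificity come from the pooled confusion
counts, with patients as the positive class.  Feature ranking uses recursive
elimination on the linear SVM (drop the smallest-|weight| feature, refit),
with single-fit weight magnitude available as the cheaper alternative; ties
from duplicated columns are broken by column order and logged.

# The synthetic cohort

The generator is the package's ground-truth instrument, and its defaults are
the study conditions: 34 patients + 32 controls, 200 volumes at TR = 2 s,
band-limited 0.01–0.08 Hz signal, 4 covariance states with sticky Markov
switching (self-transition 0.9), AR(1) temporal coloring (φ = 0.3), and
patient-only Fisher-z shifts on designated default-mode/sensorimotor edge
pairs (three positive, one negative, |z| = 0.5 — the sign pattern of the
motivating study's edge table, with magnitudes sized for detectability at
n = 66 rather than copied from t values, which are not effect sizes).

Each state's correlation matrix is Σⱼ = (1 − w)·B + w·vⱼvⱼᵀ: a modular base
B (3 modules, within-module r = 0.35) shared by all states, plus a
state-specific ±1 sign pattern vⱼ — one dominant connectivity mode per
state, which is how empirical brain-state decompositions actually differ
(a leading FC component whose topography changes, on top of stable network
structure).  Two random sign patterns disagree on about half the edges, so
the pairwise state separation on the Fisher-z scale is ≈ 2·atanh(w)·√(E/2).
The generator enforces a separation floor before accepting a draw; the
default floor is derived from the measurement noise of the windowed
estimates themselves: a 100 s window of 0.07 Hz-wide band-limited signal
carries roughly 14 effective samples, giving a per-edge z noise SD near
0.27, and the floor demands centroid separation of twice the resulting
noise norm, 2·√E·0.27.  Solving 2·atanh(w)·√(E/2) ≥ 2·√E·0.27 gives
w ≥ tanh⁻¹-free ≈ 0.37 independent of the region count, hence the default
w = 0.4.  With a non-binding floor the planted states are *not* reliably
recoverable under the default windowing — the mixing of ~20 s dwell times
inside 100 s windows softens the SSE elbow — which is precisely why the
floor is part of the generative conditions rather than decoration.

The gradient track plants a 1-D manifold: voxels carry an ascending latent
coordinate in [0, 1], profiles across parcels are Gaussian bumps of that
coordinate (correlation length 0.1) plus i.i.d. noise, and patients receive
a latent-coordinate offset in designated regions (implemented as the
additive profile perturbation that offset induces).  Between-subject
variability enters as a smooth per-subject warp of the latent axis —
global shift (SD 0.05), stretch (SD 0.1), and a quadratic bend (SD 0.2).
Two design points matter here.  A smooth warp, rather than independent
regional offsets, keeps every subject's affinity graph connected.  And the
nonlinear bend term is essential: per-subject z-scoring of gradient
components absorbs any (near-)affine transform, so with a purely affine
warp the between-subject variance of regional scores collapses to the
profile-noise floor and every group contrast becomes degenerate (|t| in
the hundreds).  Under the full warp model the default planted offset of
0.03 latent units is about 2 between-subject SDs of the regional gradient
score, satisfying the ≥ 1 SD floor the recovery analyses assume while
keeping group inference non-trivial.  One consequence of per-subject
z-scoring is worth knowing: a focal planted shift slightly displaces all
other voxels' standardized scores, so secondary regions can show genuine
compensatory group differences — gradient maps are interpretable relative
to the subject's global mean, not absolutely.  Clinical covariates emulate the demographic
table of the motivating study (patient age 10.41 ± 1.376 years, control age
11.28 ± 2.439, five cognition scores for patients only, right-skewed disease
duration); requested score–gradient correlations are planted by mixing the
standardized gradient score into the score at weight r versus √(1 − r²)
noise.  Sex ratios are free configuration — the source tables are internally
inconsistent about them, so the generator does not try to reproduce their
test statistics.

What the generator does *not* emulate: scanner physics, head motion, spatial
3-D structure (voxels are abstract units with labels and an order, which is
also why cluster correction uses chain adjacency), inter-regional
hemodynamic differences, and non-Gaussian BOLD artifacts.  Passing tests
therefore demonstrate that the pipeline recovers the structure this model
plants at realistic sizes and noise levels — not that any specific clinical
result will replicate on real data.

# Numerical choices and degenerate inputs

* Correlations are clipped to ±(1 − 1e−7) before atanh, so z values are
  always finite; a region constant within a window yields zero correlations
  and a warning rather than an error.
* The band-pass filter is a zero-phase (forward–backward) Butterworth of
  order 4 per pass; series shorter than 12 × order samples are rejected
  rather than silently transients-dominated.
* The elbow search normalizes both axes, so SSE units cancel; a non-monotone
  SSE curve (restart noise) is re-fit with triple the restarts before the
  search.
* Eigen-decomposition is done on the symmetric conjugate of the diffusion
  operator, which is numerically better conditioned than the non-symmetric
  operator itself.
* Procrustes falls back to per-component sign matching when the
  cross-product is rank deficient (logged); z-scoring refuses zero-variance
  components.
* All randomness flows from one master seed through a deterministic integer
  fan-out, so any subject, stage, or restart is individually reproducible;
  derived seeds stay inside the 32-bit range.

# Problem sizes used by the validation suite

The test and acceptance workloads run the default study design where the
claim depends on it (66 subjects, T = 200, L = 50, s = 1, k = 2..8, 20
restarts, 20 master seeds for state recovery; 2000 null features for test
calibration) and reduced sizes elsewhere (P = 30 regions for the state
track, one 100–150-voxel network for end-to-end runs, a few hundred
permutations for cluster nulls).  These reductions are package choices that
keep the suite's statistical claims intact: calibration bands and
sensitivity thresholds were chosen for the sizes actually run.

# Known limitations

* Window length, step, and band edges interact: the defaults inherit the
  motivating design and are not re-derived from the data.
* The elbow criterion is a geometric heuristic; on cohorts whose state
  mixing is strong relative to separation it can prefer k one above the
  planted value, which is why model selection is validated as a
  distribution over seeds rather than a single run.
* Gradient "smoothing" is a no-op absent geometry; on real surface data a
  geodesic smoother should replace the hook.
* The permutation cluster correction assumes exchangeability of subjects
  under the null; covariates enter the statistic but not the permutation
  scheme (no Freedman–Lane refinement).
* LOOCV estimates have high variance at n = 66; the 5-fold scheme is
  provided and preferred for anything comparative.
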