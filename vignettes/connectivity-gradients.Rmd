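---
title: "Connectivity gradients on surface meshes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity gradients on surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conngrad)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
data generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## The pipeline in one paragraph

A vertex-wise structural connectome is a nonnegative matrix whose row `i` is
the streamline-weight profile of seed vertex `i` over all targets. The
pipeline sparsifies each row at a percentile, measures profile similarity
with a cosine (or normalized-angle) kernel, and embeds the resulting affinity
graph with diffusion maps. The leading eigenvectors — the *gradients* — are
continuous spatial axes along which connection profiles change; their
three-dimensional Euclidean norm per vertex — the *eccentricity* — indexes
how strongly differentiated a vertex's connectivity is. Downstream stages
relate eccentricity to nodal connectome summaries and scalar maps under
spatial-autocorrelation-aware inference, derive analogous gradients from
cortical depth-profile covariance, and use gradients to predict network
labels and edgewise functional connectivity.

## Diffusion map embedding

Given a symmetric nonnegative affinity `A` with degrees `d_i`:

1. anisotropic normalization `L = D^-alpha A D^-alpha` with `alpha = 0.5`,
   which removes the first-order influence of sampling density while
   retaining the manifold geometry;
2. the random-walk transition matrix `P = D_L^{-1} L`, eigendecomposed
   through its symmetric conjugate `D_L^{1/2} P D_L^{-1/2}` (numerically a
   symmetric problem; eigenvalues are real and the decomposition is
   deterministic);
3. the trivial pair (eigenvalue 1, constant vector) is discarded; component
   `c` is the eigenvector `psi_c` scaled by `lambda_c / (1 - lambda_c)`.

The `lambda / (1 - lambda)` scaling is the "automated diffusion time"
convention: it equals the sum of `lambda^t` over all positive integer times
`t`, i.e. a multi-scale aggregation rather than a single diffusion horizon.
A fixed-time mode (`lambda^t`) is available through the `diffusion_time`
argument. Eigenvector signs are intrinsically arbitrary; we fix them by
making each component's largest-magnitude entry positive, which makes runs
reproducible, and leave residual cross-dataset sign and rotation ambiguity
to Procrustes alignment.

Degenerate inputs are rejected rather than repaired: a disconnected affinity
graph (or a nontrivial eigenvalue within `1e-12` of 1) is an error, because
the embedding of a disconnected graph mixes per-component constants with
geometry.

*Variance explained* is reported as `lambda_c / sum(lambda)` over the
positive nontrivial spectrum. This convention is recorded here because the
fraction is only interpretable relative to it; other conventions (squared
eigenvalues, retained-only denominators) yield different percentages from
the same embedding.

## Affinity construction

Row sparsification keeps, per row, the entries at or above that row's
`percentile` value (default 75), using R's default linear interpolation
between order statistics. The rule is inclusive, so tied entries at the
threshold all survive and a constant row survives whole (with a warning) —
ties must not be broken by storage order. Sparsification precedes the
kernel. The cosine kernel is used for nonnegative connectivity profiles; the
normalized-angle kernel `1 - acos(cos_ij)/pi` is used where profiles can be
negative (MPC matrices), mapping antiparallel profiles to 0 rather than -1.

## Surface geometry

Geodesic distances are shortest paths on the mesh edge graph with Euclidean
edge lengths — not exact polyhedral geodesics. Graph geodesics carry a small
upward bias on coarse meshes, but every use here (smoothing kernels,
connectivity distance, spatial weights) is relative, so the bias cancels;
the choice buys determinism and simplicity. Smoothing uses a geodesic
Gaussian kernel with `sigma = fwhm / sqrt(8 log 2)`, truncated at 3 sigma
(configurable; the truncation bounds cost and its effect is below the
kernel's own discretization error), and normalized to sum to one over each
*target* vertex. Target-normalization means constants are fixed points and
no mass leaks across the region-of-interest boundary; the smoothing operator
is linear and variance-reducing, which the tests assert directly.
Connectomes are smoothed along the seed-vertex axis by default — the minimal
reading of smoothing "on the surface" for a seeds-by-targets matrix — with a
both-axes option when targets also live on the mesh.

## Moran spectral randomization

Associations between cortical maps cannot be tested with ordinary regression
p-values: both maps are spatially smooth, the effective sample size is far
below the vertex count, and the F statistic's null distribution is wrong.
The package's inference engine builds Moran eigenvector maps (MEMs) — the
eigenvectors of the doubly-centered spatial weight matrix `H W H` — which
form an orthonormal basis of spatial patterns ordered by autocorrelation.
A surrogate for map `x` flips the signs of its MEM coefficients at random
(the singleton procedure), preserving the mean, variance, Moran's I, and the
full autocorrelation spectrum `{|r_i|}` of the original map exactly; the
constructed surrogate is rescaled to the sample variance of `x`, which is a
no-op for a full-rank basis and never perturbs Moran's I (a scale-free
statistic). The test fits `y ~ 1 + x` on the data and on 1000 surrogates of
the *response* map and reports `p = (1 + #{F_surr >= F_obs}) / (1 + n_surr)`
— the conservative randomization convention that avoids zero p-values; its
floor is `1/(n_surr + 1)`.

The spatial weight matrix behind the basis is a genuinely open choice; both
binary mesh adjacency and inverse-edge-length weights are provided (default:
inverse distance, recorded in the basis object), and the calibration test
passes under both. The acceptance suite verifies the property that justifies
the machinery: on independent autocorrelated map pairs the surrogate test
rejects at close to the nominal 5% while the parametric F test's rejection
rate is an order of magnitude too high.

## Microstructural profile covariance

Depth profiles enter as a parcels-by-depths intensity matrix (the deepest
sample assumed already removed upstream where partial-volume effects demand
it; the package consumes profiles as given and records the depth count).
The stage order is fixed: anatomical-axis trend correction (per-depth linear
residualization plus the grand mean), then parcellation (unweighted means,
ascending label order), then the MPC matrix, then its gradient. MPC is the
partial correlation of each profile pair controlling for the unweighted mean
profile of the input; it is algebraically identical to correlating
residuals after regressing each profile on the mean profile, which is the
oracle the tests compare against at `1e-10`. Profiles collinear with the
mean profile make the partial correlation undefined; such entries are
flagged `NA` with a warning rather than silently clamped. Negative partial
correlations are retained before the (negative-tolerant) normalized-angle
kernel; a `zero_negative` flag reproduces the common alternative. Note that
MPC is invariant to a global affine intensity change but *not* to per-parcel
rescaling: the controlled covariate is the mean profile of the input, which
per-parcel rescaling alters. This is a property of the definition, not an
implementation accident, and is why profiles must share intensity units.

## Prediction models

Network classification is multinomial logistic regression (softmax, first
label level as the zero-coefficient reference) of per-vertex labels on the
first three gradients, fitted by maximum likelihood with a ridge penalty of
`1e-8` whose only purpose is to keep coefficients finite under perfect
separation — separable synthetic labels are the expected case, and the fit
warns when it stops at the iteration cap there. Agreement is Cohen's kappa;
if both labelings are the same constant, kappa is defined as 1.

Edgewise functional connectivity is regressed on the Euclidean distance
between vertex pairs in gradient space with a best-first CART tree: at each
step the (leaf, feature, threshold) split with the largest total
squared-error reduction is taken, subject to both children holding at least
`min_leaf = 20` samples, stopping at `max_splits = 20` internal nodes.
The split-count cap is a budget on tree complexity that depth-limited
implementations cannot express, which is why the tree is implemented in the
package (an independent CART library cross-checks the single-split case in
the tests). All tie-breaks are fixed — lowest feature index, lowest
threshold, earliest-created leaf — so fits are deterministic. Evaluation is
the Pearson correlation between predicted and empirical edge values per
subject, and per vertex over the edges incident to it pooled across
subjects.

Group-level gradients per cross-validation fold are the vertex-wise mean of
the fold's subject gradients after Procrustes alignment to the first
subject. The alternative — embedding the fold-mean connectome — is a
coarser aggregate that discards subject-level spectral variability; the
mean-of-aligned convention also yields the rotation-diagnostic report
(5th/50th/95th percentiles of sign-adjusted rotation diagonals) that
quantifies how stable manifold orientations are across subjects.

## The synthetic study

The generator plants ground truth with the statistical structure the
pipeline assumes, at a desk scale chosen once:

- **Mesh**: icosphere with 2 subdivisions — 162 vertices, 320 triangles,
  ~100 mm diameter — with a geodesic-cap ROI of half the vertices (81), the
  smallest mesh on which an 80-vertex-scale region supports stable
  embeddings, Moran bases, and >= 10-vertex network classes.
- **Latent axes**: 3 orthonormal, zero-mean combinations of low-rank Moran
  eigenvectors with power-law coefficient decay (`smoothness = 2`), i.e.
  smooth by construction (Moran's I near 1).
- **Connectome**: row `i` is a Gaussian bump `exp(-||l_i - c_t||^2 / tau)`
  over 400 target anchors drawn uniformly in latent range, `tau` set to half
  the median squared vertex-anchor distance; cosine affinity of such rows is
  a smooth function of latent distance, which makes planted-axis recovery a
  well-posed experiment. Truncated Gaussian noise (`sd = 0.1` per subject)
  is added on the weight scale. Target anchors are drawn once per
  *population* and shared by all cohorts, as real datasets share template
  target vertices.
- **Cohorts**: two cohorts of 75 subjects (a discovery/replication design)
  share the population anatomy, labels, maps and profiles and differ only in
  per-subject noise.
- **FC**: `tanh(1 - 0.5 * latent distance)` plus symmetric noise
  (`sd = 0.1`), clipped to [-1, 1] with unit diagonal — correlation-like by
  construction and strictly decreasing in latent distance when noise-free.
- **Labels**: 4 networks as nearest-centroid (Voronoi) cells of
  vertex-anchored centroids in latent space, redrawn until every network has
  at least 10 vertices (a classifier precondition); 4 rather than the 7
  canonical resting-state networks because 81 vertices cannot support 7
  classes of 10.
- **Maps**: mixtures of latent-geometry signal and MEM-based autocorrelated
  noise — one strongly coupled (myelin-like, weight 0.8), one moderately and
  negatively coupled (thickness-like, 0.45), one pure spatial noise
  (curvature-like) — so the association stage sees both real and null
  effects.
- **Profiles**: 200 parcels x 17 depths (18 intracortical sampling surfaces
  with the innermost removed), a shared mean profile plus a mid-depth
  loading scaled by a smooth parcel ordering (`axis_strength = 1`,
  `noise_sd = 0.05`), with the anatomical trend coordinate drawn
  independently of the planted axis; 200 parcels stands in for the
  ~1000-parcel histological parcellations of real studies.

What the generator does **not** emulate: realistic cortical folding (the
mesh is a sphere, so geodesic-vs-Euclidean discrepancies are mild),
distance-dependent tractography biases (false-positive short-range and
missing long-range streamlines), inter-subject anatomical variability
(cohorts share one mesh; only noise varies), hemispheric asymmetries, and
any acquisition physics. Passing tests therefore demonstrate that the
algorithms recover known structure under the stated statistical model — not
that they are robust to the systematic artefacts of real diffusion MRI.

One operating-point subtlety is documented rather than hidden: with 75%
row sparsification, subject-level noise of 0.1 on the weight scale leaves
planted-axis recovery statistically unchanged relative to noise-free data
(the zero-truncated noise slightly densifies sub-threshold entries), while
noise 0.3 degrades it clearly. The monotone-degradation test treats the
two lowest levels as statistically tied (slack 0.005, above the measured
systematic effect and sampling error) and requires strict degradation at
0.3.

## Numerical conventions

- Percentiles everywhere use linear interpolation between order statistics
  (R's default quantile type 7); thresholds are inclusive.
- Eigendecompositions of symmetric problems use the symmetric solver;
  eigenvector signs are fixed by the largest-magnitude-entry rule.
- Moran basis null-space removal: eigenvalues below `1e-10` of the spectral
  radius are dropped (this removes the constant vector).
- Procrustes uses the SVD solution `R = U V'` of `S' Ref`; rank-deficient
  cross-products warn and proceed (the SVD solution remains the minimizer).
- The k-fold split is a seeded shuffle followed by contiguous chunking, the
  first `n mod k` folds taking the extra subject.
- Problem sizes in the test and acceptance suites (162-vertex meshes, 75
  subjects, 199-surrogate calibration with 1000 replicates, 500-replicate
  calibration in the acceptance script) are the package's chosen study
  conditions; they keep any machine's run in minutes while leaving all
  statistical margins wide.

## Known limitations

- Graph geodesics overestimate true surface distance on coarse meshes.
- The embedding assumes a connected affinity graph; heavily sparsified
  empirical connectomes may need a lower sparsity percentile.
- MPC requires profiles in shared intensity units (see above).
- The FC tree uses a single scalar distance feature by default; per-axis
  distances are available behind `per_axis = TRUE` but were not the default
  because the scalar-distance model is the minimal, most interpretable
  reading of gradient-space prediction.
- Interhemispheric connections are out of scope: gradients are computed per
  hemisphere and merged by Procrustes (`hemisphere_merge()`).
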