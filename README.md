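# conngrad

Structural connectivity gradients on cortical surface meshes: vertex-wise
connectome construction, diffusion-map manifold learning, spatially-corrected
statistics, microstructural profile covariance, and gradient-based prediction
of functional network organization.

## The problem

Regions such as the temporal lobe are not a mosaic of discrete parcels: their
extrinsic connectivity changes smoothly across the cortical sheet. A compact
way to describe that organization is a small set of *connectivity gradients* —
spatial eigenvectors of a low-dimensional embedding of the vertex-wise
connectome — plus a scalar *eccentricity* map that marks how differentiated
each vertex's connection profile is. `conngrad` implements that analysis as a
tested R pipeline:

1. **Connectome construction.** Weighted streamline endpoint records
   (`x1 y1 z1 x2 y2 z2 weight`) are assigned to their Euclidean-nearest
   surface vertices; a streamline is discarded if either terminus lies more
   than 3 mm from a vertex. Connectomes are smoothed on the surface with a
   geodesic Gaussian kernel (20 mm FWHM).
2. **Gradients.** Each connectivity profile is row-sparsified at the 75th
   percentile, converted to a cosine affinity
   `A_ij = <r_i, r_j> / (||r_i|| ||r_j||)`, and embedded by diffusion maps:
   with degrees `d_i = sum_j A_ij`, the anisotropic kernel
   `L = D^-alpha A D^-alpha` (alpha = 0.5) is row-normalized into a transition
   matrix `P` whose nontrivial eigenvectors `psi_c`, scaled by
   `lambda_c / (1 - lambda_c)` (automated diffusion time), are the gradients
   G1, G2, G3, ... Subject and hemisphere gradient sets are aligned by
   orthogonal Procrustes; `ecc_v = sqrt(G1_v^2 + G2_v^2 + G3_v^2)` is the
   manifold eccentricity.
3. **Connectome summaries.** Degree centrality (sum of connection weights)
   and connectivity distance (mean geodesic distance of each node's
   suprathreshold connections, 80th percentile).
4. **Spatial statistics.** Cortical maps are spatially autocorrelated, so
   map-map associations are tested with Moran spectral randomization:
   surrogates built by random sign-flipping of a map's Moran-eigenvector
   coefficients preserve its mean, variance and Moran's I exactly; p-values
   are percentile ranks of the observed F statistic among 1000 surrogate
   fits, with Benjamini-Hochberg FDR across tests.
5. **Microstructure.** Parcel-by-depth intensity profiles are trend-corrected
   along an anatomical axis, converted to a microstructural profile
   covariance (MPC) matrix — partial correlations of profile pairs
   controlling for the mean profile — and embedded (90% sparsity,
   normalized-angle kernel) into cytoarchitectural gradients.
6. **Prediction.** Multinomial logistic regression of network labels on the
   first three gradients (5-fold cross-validation, Cohen's kappa) and
   best-first CART regression of edgewise functional connectivity on
   gradient-space Euclidean distances (minimum leaf 20, at most 20 splits),
   evaluated per subject and per vertex, within and across cohorts.

Because the imaging datasets behind such analyses are restricted-access, the
package ships a first-class synthetic-data generator: smooth latent axes are
planted on an icosphere mesh and drive the connectome, functional
connectivity, network labels and depth profiles, so every stage runs against
a known ground truth.

## Worked example

```r
library(conngrad)

pop    <- make_population(seed = 1)          # 162-vertex mesh, 81-vertex ROI
bundle <- make_bundle(pop, subjects = 75, seed = 1)

gg  <- group_gradients(bundle$connectomes, mesh = pop$mesh, k = 3)
ecc <- eccentricity(gg$group)
print(gg$report)
#> alignment_report: sign-adjusted rotation diagonals p5/p50/p95 = 0.994/0.999/1.000

# do the recovered gradients span the planted axes?
min(cancor(gg$group, pop$latent$coords)$cor)
#> [1] 0.9696

# spatially-corrected association between eccentricity and a myelin-like map
res <- spatial_association_test(ecc, pop$maps$myelin_proxy, pop$basis,
                                n_surr = 1000, seed = 1)
print(res)
#> r = 0.588, F = 41.73, p_moran = 0.039 (1000 surrogates)
```

The numbers mean: subject-to-reference rotations are near-identity (diagonals
about 0.99), the three embedding axes recover the planted latent axes with
worst-case canonical correlation 0.97, and eccentricity tracks the
myelin-proxy map (r = 0.59) with a surrogate-based p-value that honours the
maps' spatial smoothness.

The full study is organized as numbered drivers under `analysis/`
(`01_simulate.R` ... `06_predict.R`), each a thin narrative script over the
package functions that writes its tables under `results/`.

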