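Package: conngrad
Title: Structural Connectivity Gradients on Cortical Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vertex-wise structural connectome construction from weighted
    streamline endpoints, diffusion-map connectivity gradients with Procrustes
    alignment and manifold eccentricity, spatial-autocorrelation-aware
    association testing via Moran spectral randomization, microstructural
    profile covariance gradients from cortical depth profiles, and
    gradient-based prediction of functional network organization. Includes a
    synthetic-data generator that plants low-dimensional latent axes on
    triangulated surface meshes so the full pipeline can be exercised and
    validated without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    nnet,
    stats,
    utils,
    xml2
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
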