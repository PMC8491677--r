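# Synthetic surface/connectome data with the statistical structure the
# pipeline assumes: smooth low-dimensional latent axes planted on a mesh
# generate a nonnegative connectome (so the embedding has known ground
# truth), functional connectivity decays with latent-space distance, scalar
# maps are spatially autocorrelated, network labels are separable in latent
# space, and depth profiles are driven by a single latent microstructural
# axis. All generators are pure functions of (parameters, seed).

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v / sqrt(1 + phi^2), triangles = f)
}

subdivide_sphere <- function(v, f) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  midpoint <- new.env(hash = TRUE)
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  get_mid <- function(a, b) {
    k <- key(a, b)
    id <- midpoint[[k]]
    if (!is.null(id)) return(id)
    m <- (verts[[a]] + verts[[b]]) / 2
    m <- m / sqrt(sum(m^2))
    verts[[length(verts) + 1L]] <<- m
    midpoint[[k]] <- length(verts)
    length(verts)
  }
  newf <- matrix(0L, nrow(f) * 4L, 3L)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1L]; b <- f[t, 2L]; c <- f[t, 3L]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    newf[(t - 1L) * 4L + 1:4, ] <- rbind(
      c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = do.call(rbind, verts), triangles = newf)
}

#' Generate an icosphere test mesh with a geodesic-cap ROI
#'
#' Icosahedron subdivided `subdivisions` times and scaled to ~100 mm
#' diameter (vertex count `10 * 4^subdivisions + 2`). The ROI is a geodesic
#' cap around a seed-chosen center vertex containing `roi_fraction` of the
#' vertices (nearest by angular distance, ties by index), so it is connected
#' by construction.
#'
#' @param subdivisions number of subdivision rounds (>= 1).
#' @param roi_fraction fraction of vertices in the ROI, in (0, 1].
#' @param seed integer seed (chooses the cap center).
#' @param radius_mm sphere radius (default 50).
#' @return a `surface_mesh`.
#' @export
make_mesh <- function(subdivisions = 2, roi_fraction = 0.5, seed = 1,
                      radius_mm = 50) {
  if (subdivisions < 1) stop("subdivisions must be >= 1")
  if (roi_fraction <= 0 || roi_fraction > 1) {
    stop("roi_fraction must be in (0, 1]")
  }
  ico <- icosahedron()
  for (i in seq_len(subdivisions)) {
    ico <- subdivide_sphere(ico$vertices, ico$triangles)
  }
  v <- ico$vertices * radius_mm
  n <- nrow(v)
  n_roi <- ceiling(roi_fraction * n)
  if (n_roi < 20L) stop("ROI would contain fewer than 20 vertices")
  set.seed(seed)
  center <- sample.int(n, 1L)
  ang <- acos(pmin(pmax(tcrossprod(ico$vertices,
                                   ico$vertices[center, , drop = FALSE]),
                        -1), 1))
  roi <- rep(FALSE, n)
  roi[order(ang, seq_len(n))[seq_len(n_roi)]] <- TRUE
  surface_mesh(v, ico$triangles, roi_mask = roi, hemisphere = "left")
}

#' Plant smooth latent axes on a mesh ROI
#'
#' Axes are random linear combinations of Moran eigenvector maps of the ROI
#' adjacency with coefficient power-law decay in Moran rank (`sd_i =
#' i^-smoothness`), then orthonormalized. Larger `smoothness` concentrates
#' energy in low-rank (smooth) patterns, i.e. higher Moran's I. Each axis is
#' zero-mean with unit norm; axes are mutually orthogonal.
#'
#' @param mesh a `surface_mesh`.
#' @param k number of axes (>= 1, <= ROI size - 1).
#' @param smoothness power-law decay exponent of the MEM coefficients.
#' @param seed integer seed.
#' @return object of class `latent_axes`: list with `coords`
#'   (ROI vertices x k), `smoothness`, `seed`.
#' @export
plant_axes <- function(mesh, k = 3, smoothness = 2, seed = 1) {
  if (k < 1L) stop("k must be >= 1")
  nroi <- sum(mesh$roi_mask)
  if (k > nroi - 1L) stop("k must be <= ROI size - 1")
  basis <- moran_basis(build_adjacency(mesh, "binary", roi_only = TRUE))
  m <- ncol(basis$mems)
  set.seed(seed)
  coef <- matrix(stats::rnorm(m * k), m, k) * seq_len(m)^(-smoothness)
  raw <- basis$mems %*% coef
  q <- qr.Q(qr(raw))
  q <- fix_column_signs(q)
  structure(list(coords = q, smoothness = smoothness, seed = seed),
            class = "latent_axes")
}

# latent coordinates standardized to unit variance per axis
latent_std <- function(latent) {
  co <- latent$coords
  co * sqrt(nrow(co) - 1)
}

#' Generate a connectome with planted latent structure
#'
#' Row `i`'s profile over targets is a Gaussian bump in latent space,
#' `exp(-||l(i) - c_t||^2 / tau)` for target anchors `c_t`, plus truncated
#' Gaussian noise. Cosine affinity between such rows is a smooth function of
#' latent distance, so a diffusion map embedding of the noise-free matrix
#' provably recovers the planted axes.
#'
#' @param latent a `latent_axes`.
#' @param n_targets number of abstract targets (columns).
#' @param noise_sd truncated-Gaussian noise level (>= 0) on the weights.
#' @param seed integer seed.
#' @param tau Gaussian-bump bandwidth in squared latent distance; default
#'   half the median squared vertex-anchor distance (scale-free).
#' @param anchors optional pre-drawn n_targets x k anchor matrix, to share
#'   target identities across subjects of a cohort.
#' @return a `connectome` with seeds = ROI vertices.
#' @export
make_connectome <- function(latent, n_targets = 400, noise_sd = 0, seed = 1,
                            tau = NULL, anchors = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  L <- latent_std(latent)
  k <- ncol(L)
  set.seed(seed)
  if (is.null(anchors)) {
    rng <- apply(L, 2L, range)
    anchors <- sapply(seq_len(k), function(j) {
      stats::runif(n_targets, rng[1L, j], rng[2L, j])
    })
    anchors <- matrix(anchors, n_targets, k)
  }
  d2 <- outer(rowSums(L^2), rowSums(anchors^2), "+") -
    2 * tcrossprod(L, anchors)
  d2[d2 < 0] <- 0
  if (is.null(tau)) tau <- stats::median(d2) / 2
  w <- exp(-d2 / tau)
  if (noise_sd > 0) {
    w <- pmax(w + matrix(stats::rnorm(length(w), sd = noise_sd),
                         nrow(w), ncol(w)), 0)
  }
  new_connectome(w, seq_len(nrow(L)), seq_len(ncol(w)))
}

#' Generate functional connectivity coupled to latent distance
#'
#' `fc_ij = tanh(intercept - slope * ||l(i) - l(j)||) + noise`, symmetrized,
#' clipped to [-1, 1], unit diagonal. The tanh link keeps values in the range
#' of empirical correlations; with `noise_sd = 0` the off-diagonal is a
#' strictly decreasing function of latent distance.
#'
#' @param latent a `latent_axes`.
#' @param slope decay of FC with latent distance (>= 0).
#' @param noise_sd Gaussian noise level on the symmetrized matrix.
#' @param seed integer seed.
#' @param intercept FC level at zero latent distance (pre-tanh).
#' @return symmetric FC matrix over ROI vertices.
#' @export
make_fc <- function(latent, slope = 0.5, noise_sd = 0.1, seed = 1,
                    intercept = 1) {
  L <- latent_std(latent)
  d <- as.matrix(stats::dist(L))
  fc <- tanh(intercept - slope * d)
  if (noise_sd > 0) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(length(fc), sd = noise_sd), nrow(fc))
    fc <- fc + (noise + t(noise)) / 2
  }
  fc <- pmin(pmax((fc + t(fc)) / 2, -1), 1)
  diag(fc) <- 1
  dimnames(fc) <- NULL
  fc
}

#' Generate network labels separable in latent space
#'
#' Labels are the nearest of `n_networks` centroids placed at the latent
#' coordinates of seed-chosen vertices; every network is nonempty (each
#' centroid vertex is its own nearest centroid). Centroid draws are
#' rejected and redrawn while any network holds fewer than `min_size`
#' vertices, so downstream classifier preconditions are met by
#' construction; the procedure is deterministic given the seed.
#'
#' @param latent a `latent_axes`.
#' @param n_networks number of networks.
#' @param seed integer seed.
#' @param min_size smallest admissible network size.
#' @return factor of per-vertex labels (`N1` ... `Nk`).
#' @export
make_labels <- function(latent, n_networks = 4, seed = 1, min_size = 1) {
  L <- latent_std(latent)
  n <- nrow(L)
  if (n_networks > n) stop("more networks than vertices")
  if (min_size * n_networks > n) stop("min_size infeasible for vertex count")
  set.seed(seed)
  for (attempt in 1:500) {
    cent <- L[sample.int(n, n_networks), , drop = FALSE]
    d2 <- outer(rowSums(L^2), rowSums(cent^2), "+") - 2 * tcrossprod(L, cent)
    lab <- max.col(-d2, ties.method = "first")
    if (min(tabulate(lab, n_networks)) >= min_size) {
      return(factor(paste0("N", lab), levels = paste0("N", seq_len(n_networks))))
    }
  }
  stop("could not place networks of at least ", min_size, " vertices")
}

#' Generate a spatially autocorrelated scalar map
#'
#' `map = sum_i b_i MEM_i` with independent Gaussian `b_i` whose standard
#' deviation decays as `rank^-decay`; standardized to mean 0, sd 1.
#' `decay = 0` gives spatial white noise (expected Moran's I of
#' `-1/(n-1)`); large `decay` concentrates variance in smooth patterns.
#'
#' @param basis a `moran_basis`.
#' @param decay power-law decay exponent over Moran rank.
#' @param seed integer seed.
#' @return standardized per-vertex map.
#' @export
make_autocorr_map <- function(basis, decay = 1, seed = 1) {
  m <- ncol(basis$mems)
  set.seed(seed)
  b <- stats::rnorm(m) * seq_len(m)^(-decay)
  map <- drop(basis$mems %*% b)
  (map - mean(map)) / stats::sd(map)
}

#' Generate streamline endpoints realizing a connectome
#'
#' The inverse of endpoint assignment, for round-trip testing: samples
#' streamline (seed, target) pairs proportional to connectome weights and
#' places termini within `jitter_mm` of their vertices. A fraction of
#' streamlines are "orphans" whose seed-side terminus lies at the mesh
#' center, at least twice the 3 mm discard radius from every vertex, to
#' exercise the discard rule unambiguously.
#'
#' @param mesh the `surface_mesh` whose ROI indexes the connectome seeds and
#'   whose full vertex set indexes the targets.
#' @param connectome a `connectome` with `ncol(weights) ==
#'   nrow(mesh$vertices)`.
#' @param n_streamlines number of streamlines to sample.
#' @param jitter_mm terminus displacement radius, must be < 3 mm.
#' @param orphan_fraction per-streamline probability of being an orphan.
#' @param seed integer seed.
#' @return list with `endpoints` (an `endpoint_set`, unit weights),
#'   `pair_counts` (the sampled seed x target count matrix), `n_orphans`.
#' @export
make_endpoints <- function(mesh, connectome, n_streamlines = 1000,
                           jitter_mm = 0, orphan_fraction = 0, seed = 1) {
  if (jitter_mm >= 3) stop("jitter_mm must be < 3 (the discard radius)")
  if (jitter_mm < 0) stop("jitter_mm must be >= 0")
  w <- connectome$weights
  roi <- which(mesh$roi_mask)
  if (nrow(w) != length(roi) || ncol(w) != nrow(mesh$vertices)) {
    stop("connectome shape does not match mesh ROI x vertices")
  }
  set.seed(seed)
  orphan <- stats::runif(n_streamlines) < orphan_fraction
  n_real <- sum(!orphan)
  counts <- matrix(0, nrow(w), ncol(w))
  cells <- integer(0)
  if (n_real > 0L) {
    cells <- sample.int(length(w), n_real, replace = TRUE,
                        prob = as.vector(w))
    counts[] <- tabulate(cells, nbins = length(w))
  }
  cell_rows <- ((cells - 1L) %% nrow(w)) + 1L
  cell_cols <- ((cells - 1L) %/% nrow(w)) + 1L
  a <- mesh$vertices[roi[cell_rows], , drop = FALSE]
  b <- mesh$vertices[cell_cols, , drop = FALSE]
  jitter_pts <- function(p) {
    if (jitter_mm == 0) return(p)
    u <- matrix(stats::rnorm(3L * nrow(p)), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    p + u * stats::runif(nrow(p), 0, jitter_mm)
  }
  a <- jitter_pts(a)
  b <- jitter_pts(b)
  n_orph <- sum(orphan)
  if (n_orph > 0L) {
    center <- matrix(stats::rnorm(3L * n_orph, sd = 0.5), ncol = 3L)
    if (min(sqrt(rowSums((mesh$vertices)^2))) < 6) {
      stop("mesh too small to place orphans 2x the discard radius away")
    }
    bt <- mesh$vertices[sample.int(nrow(mesh$vertices), n_orph,
                                   replace = TRUE), , drop = FALSE]
    a <- rbind(a, center)
    b <- rbind(b, bt)
  }
  list(endpoints = endpoint_set(a, b, rep(1, nrow(a))),
       pair_counts = counts, n_orphans = n_orph)
}

#' Generate depth-intensity profiles driven by one latent axis
#'
#' `profile_p = shared mean profile + axis_value(p) * depth loading + noise`,
#' with `axis_value` a smooth 1D ordering over parcels. Emulates cortical
#' depth-wise staining-intensity profiles whose covariance encodes a single
#' microstructural axis. An optional linear anterior-posterior trend in
#' `axis_coordinate` can be added to exercise trend correction.
#'
#' @param n_parcels,n_depths profile matrix dimensions (`n_depths >= 3`).
#' @param axis_strength amplitude of the planted axis.
#' @param noise_sd i.i.d. Gaussian noise on intensities.
#' @param seed integer seed.
#' @param ap_trend slope of an added intensity trend in `axis_coordinate`.
#' @return object of class `profile_set`: list with `intensities`
#'   (parcels x depths), `depth_count`, `axis_coordinate` (mm),
#'   `planted_axis`.
#' @export
make_profiles <- function(n_parcels = 200, n_depths = 17, axis_strength = 1,
                          noise_sd = 0.05, seed = 1, ap_trend = 0) {
  if (n_depths < 3L) stop("n_depths must be >= 3")
  depth <- seq(0, 1, length.out = n_depths)
  mean_profile <- 100 - 25 * depth          # intensity drops toward white matter
  loading <- sin(pi * depth)                # mid-depth contrast
  axis_value <- seq(-1, 1, length.out = n_parcels)
  set.seed(seed)
  # anatomical position is independent of the planted microstructural axis,
  # so axis-trend correction removes drift without touching the signal
  axis_coordinate <- stats::runif(n_parcels, 0, 100)
  intens <- matrix(mean_profile, n_parcels, n_depths, byrow = TRUE) +
    axis_strength * outer(axis_value, loading) +
    ap_trend * matrix(axis_coordinate, n_parcels, n_depths) +
    matrix(stats::rnorm(n_parcels * n_depths, sd = noise_sd),
           n_parcels, n_depths)
  profile_set(intens, axis_coordinate = axis_coordinate,
              planted_axis = axis_value)
}

#' Generate the shared population structure of a synthetic study
#'
#' The anatomy and ground truth that are common to every cohort drawn from
#' the same "population": the mesh, the planted latent axes, the network
#' labels, per-vertex scalar maps (two coupled to the latent geometry with
#' different strengths, one independent autocorrelated null map), the depth
#' profiles, and the ROI Moran basis used for surrogates.
#'
#' @param subdivisions,roi_fraction,seed passed to [make_mesh()].
#' @param k,smoothness passed to [plant_axes()].
#' @param n_networks passed to [make_labels()].
#' @param n_parcels,n_depths passed to [make_profiles()].
#' @param n_targets shared connectome target anchors: the targets are the
#'   same "rest of the brain" locations for every cohort drawn from this
#'   population, exactly as datasets scanned on one template share target
#'   vertices.
#' @return object of class `synthetic_population`.
#' @export
make_population <- function(subdivisions = 2, roi_fraction = 0.5, k = 3,
                            smoothness = 2, n_networks = 4, n_parcels = 200,
                            n_depths = 17, n_targets = 400, seed = 1) {
  mesh <- make_mesh(subdivisions, roi_fraction, seed = seed)
  latent <- plant_axes(mesh, k = k, smoothness = smoothness, seed = seed + 1)
  labels <- make_labels(latent, n_networks = n_networks, seed = seed + 2,
                        min_size = 10)
  basis <- moran_basis(build_adjacency(mesh, "inverse_distance",
                                       roi_only = TRUE))
  ecc_latent <- eccentricity(latent_std(latent))
  ecc_latent <- (ecc_latent - mean(ecc_latent)) / stats::sd(ecc_latent)
  mix <- function(signal, weight, map_seed) {
    noise <- make_autocorr_map(basis, decay = 1, seed = map_seed)
    m <- weight * signal + sqrt(1 - weight^2) * noise
    (m - mean(m)) / stats::sd(m)
  }
  maps <- list(
    myelin_proxy = mix(ecc_latent, 0.8, seed + 3),
    thickness = mix(-ecc_latent, 0.45, seed + 4),
    curvature = make_autocorr_map(basis, decay = 1, seed = seed + 5)
  )
  L <- latent_std(latent)
  set.seed(seed + 7)
  rng <- apply(L, 2L, range)
  target_anchors <- sapply(seq_len(ncol(L)), function(j) {
    stats::runif(n_targets, rng[1L, j], rng[2L, j])
  })
  structure(
    list(mesh = mesh, latent = latent, labels = labels, maps = maps,
         profiles = make_profiles(n_parcels, n_depths, seed = seed + 6),
         basis = basis,
         target_anchors = matrix(target_anchors, n_targets, ncol(L)),
         seed = seed),
    class = "synthetic_population"
  )
}

#' Draw a cohort ("dataset") from a synthetic population
#'
#' Subject-level connectomes and functional connectivity share the
#' population's latent axes and target anchors but carry independent noise,
#' mirroring two subject cohorts scanned from one underlying anatomy. Also
#' builds a group-mean connectome and an endpoint realization of it for
#' round-trip exercises.
#'
#' @param population a `synthetic_population`.
#' @param subjects number of subjects.
#' @param conn_noise_sd connectome noise level per subject.
#' @param fc_noise_sd FC noise level per subject.
#' @param fc_slope decay of FC with latent distance.
#' @param seed integer cohort seed.
#' @return object of class `synthetic_bundle`: the population fields plus
#'   `connectomes` (list), `fc` (list), `connectome` (group mean over mesh
#'   targets), `fc_mean`, `endpoints`.
#' @export
make_bundle <- function(population, subjects = 75, conn_noise_sd = 0.1,
                        fc_noise_sd = 0.1, fc_slope = 0.5, seed = 1) {
  latent <- population$latent
  anchors <- population$target_anchors
  n_targets <- nrow(anchors)
  connectomes <- lapply(seq_len(subjects), function(s) {
    make_connectome(latent, n_targets = n_targets, noise_sd = conn_noise_sd,
                    seed = seed * 10000 + s, anchors = anchors)
  })
  fc <- lapply(seq_len(subjects), function(s) {
    make_fc(latent, slope = fc_slope, noise_sd = fc_noise_sd,
            seed = seed * 20000 + s)
  })
  mesh_conn <- make_connectome(latent,
                               n_targets = nrow(population$mesh$vertices),
                               noise_sd = 0, seed = seed,
                               anchors = NULL)
  fc_mean <- Reduce(`+`, fc) / length(fc)
  ep <- make_endpoints(population$mesh, mesh_conn, n_streamlines = 2000,
                       seed = seed + 1)
  structure(
    c(population[c("mesh", "latent", "labels", "maps", "profiles", "basis")],
      list(connectomes = connectomes, fc = fc, connectome = mesh_conn,
           fc_mean = fc_mean, endpoints = ep, subjects = subjects,
           seed = seed)),
    class = "synthetic_bundle"
  )
}
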