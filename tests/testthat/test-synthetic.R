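test_that("icosphere meshes have the expected counts and are deterministic", {
  for (n in 1:2) {
    mesh <- make_mesh(n, 1.0, seed = 1)
    expect_equal(nrow(mesh$vertices), 10 * 4^n + 2)
    expect_equal(nrow(mesh$triangles), 20 * 4^n)
  }
  a <- make_mesh(2, 0.5, seed = 7)
  b <- make_mesh(2, 0.5, seed = 7)
  expect_identical(a, b)
  expect_true(all(make_mesh(2, 1.0, seed = 1)$roi_mask))
  # ~100 mm diameter
  expect_equal(max(stats::dist(make_mesh(1, 1, seed = 1)$vertices)), 100,
               tolerance = 0.01)
  expect_error(make_mesh(1, 0.1, seed = 1), "20 vertices")
})

test_that("planted axes are orthonormal, zero-mean and spatially smooth", {
  mesh <- make_mesh(2, 0.5, seed = 1)
  ax <- plant_axes(mesh, k = 3, smoothness = 2, seed = 2)
  co <- ax$coords
  expect_equal(crossprod(co), diag(3), tolerance = 1e-10)
  expect_equal(colMeans(co), rep(0, 3), tolerance = 1e-10)
  expect_lt(max(abs(stats::cor(co)[upper.tri(diag(3))])), 1e-10)

  w <- build_adjacency(mesh, "binary", roi_only = TRUE)
  expect_gt(morans_i(co[, 1], w), 0.5)

  one <- plant_axes(mesh, k = 1, smoothness = 2, seed = 3)
  expect_equal(sum(one$coords^2), 1, tolerance = 1e-12)
  expect_equal(mean(one$coords), 0, tolerance = 1e-12)
  expect_error(plant_axes(mesh, k = 0), ">= 1")
})

test_that("planted connectomes are nonnegative with duplicate-row structure", {
  mesh <- make_mesh(2, 0.5, seed = 1)
  ax <- plant_axes(mesh, k = 3, smoothness = 2, seed = 2)
  # duplicate latent coordinates must give identical noise-free rows
  ax2 <- ax
  ax2$coords[2, ] <- ax2$coords[1, ]
  cn <- make_connectome(ax2, n_targets = 50, noise_sd = 0, seed = 3)
  expect_equal(cn$weights[1, ], cn$weights[2, ])

  cn <- make_connectome(ax, n_targets = 100, noise_sd = 0.2, seed = 4)
  expect_true(all(cn$weights >= 0))
  expect_error(make_connectome(ax, noise_sd = -1), ">= 0")
})

test_that("synthetic FC is a symmetric decreasing function of latent distance", {
  mesh <- make_mesh(2, 0.5, seed = 1)
  ax <- plant_axes(mesh, k = 3, smoothness = 2, seed = 2)
  fc0 <- make_fc(ax, slope = 0, noise_sd = 0)
  off <- fc0[upper.tri(fc0)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-12)

  fc <- make_fc(ax, slope = 0.5, noise_sd = 0)
  d <- as.matrix(stats::dist(ax$coords))
  ut <- upper.tri(fc)
  ord <- order(d[ut])
  expect_true(all(diff(fc[ut][ord]) <= 1e-12))
  expect_equal(fc, t(fc), tolerance = 1e-12)
  expect_equal(diag(fc), rep(1, nrow(fc)))

  fcn <- make_fc(ax, slope = 0.5, noise_sd = 0.1, seed = 5)
  expect_equal(fcn, t(fcn), tolerance = 1e-12)
  expect_true(all(abs(fcn) <= 1))
})

test_that("network labels are deterministic, exhaustive and separable", {
  mesh <- make_mesh(2, 0.5, seed = 1)
  ax <- plant_axes(mesh, k = 3, smoothness = 2, seed = 2)
  expect_identical(make_labels(ax, 4, seed = 9), make_labels(ax, 4, seed = 9))
  expect_equal(nlevels(make_labels(ax, 1, seed = 1)), 1)
  lab <- make_labels(ax, 5, seed = 3)
  expect_true(all(table(lab) > 0))
  expect_error(make_labels(ax, 10000, seed = 1), "more networks")
})

test_that("autocorrelated maps are standardized with tunable Moran's I", {
  mesh <- make_mesh(2, 100 / 162, seed = 1)
  w <- build_adjacency(mesh, "binary", roi_only = TRUE)
  basis <- moran_basis(w)
  m <- make_autocorr_map(basis, decay = 1.5, seed = 1)
  expect_equal(mean(m), 0, tolerance = 1e-12)
  expect_equal(stats::sd(m), 1, tolerance = 1e-12)
  expect_gt(morans_i(m, w), 0.5)

  # decay = 0 is spatial white noise: E[I] = -1/(n-1)
  n <- nrow(basis$mems)
  is <- vapply(1:500, function(s) {
    morans_i(make_autocorr_map(basis, decay = 0, seed = s), w)
  }, numeric(1))
  expect_equal(mean(is), -1 / (n - 1), tolerance = 4 * stats::sd(is) / sqrt(500))

  # maps with different seeds are uncorrelated on average
  rs <- vapply(1:200, function(s) {
    stats::cor(make_autocorr_map(basis, decay = 1, seed = s),
               make_autocorr_map(basis, decay = 1, seed = 10000 + s))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 4 * stats::sd(rs) / sqrt(200))
})

test_that("endpoint generation inverts endpoint assignment", {
  mesh <- make_mesh(2, 0.5, seed = 1)
  ax <- plant_axes(mesh, k = 3, smoothness = 2, seed = 2)
  cn <- make_connectome(ax, n_targets = nrow(mesh$vertices), noise_sd = 0,
                        seed = 3)
  ep <- make_endpoints(mesh, cn, n_streamlines = 400, jitter_mm = 0,
                       orphan_fraction = 0, seed = 4)
  asg <- assign_endpoints(ep$endpoints, mesh)
  expect_equal(asg$connectome$weights, ep$pair_counts)
  expect_equal(asg$n_discarded, 0)

  # orphans are discarded by the 3 mm rule, count ~ Binomial(n, fraction)
  ep <- make_endpoints(mesh, cn, n_streamlines = 1000, jitter_mm = 0,
                       orphan_fraction = 0.1, seed = 5)
  asg <- assign_endpoints(ep$endpoints, mesh)
  expect_equal(asg$n_discarded, ep$n_orphans)
  expect_lt(abs(ep$n_orphans - 100), 4 * sqrt(1000 * 0.1 * 0.9))

  e1 <- make_endpoints(mesh, cn, 100, seed = 6)
  e2 <- make_endpoints(mesh, cn, 100, seed = 6)
  expect_identical(e1, e2)
  expect_error(make_endpoints(mesh, cn, 10, jitter_mm = 3), "discard radius")
})

test_that("depth profiles carry a recoverable planted axis", {
  p1 <- make_profiles(50, 10, seed = 3)
  p2 <- make_profiles(50, 10, seed = 3)
  expect_identical(p1, p2)
  expect_error(make_profiles(50, 2), ">= 3")

  flat <- make_profiles(20, 10, axis_strength = 0, noise_sd = 0, seed = 1)
  expect_equal(nrow(unique(flat$intensities)), 1)
  expect_error(mpc_matrix(flat), "identical")
})

test_that("generated bundles satisfy downstream preconditions", {
  pop <- make_population(seed = 11)
  bundle <- make_bundle(pop, subjects = 3, seed = 11)
  nroi <- sum(pop$mesh$roi_mask)
  expect_length(pop$labels, nroi)
  expect_true(all(vapply(pop$maps, length, integer(1)) == nroi))
  expect_true(all(vapply(bundle$connectomes,
                         function(cn) all(cn$weights >= 0), logical(1))))
  for (fc in bundle$fc) {
    expect_equal(fc, t(fc), tolerance = 1e-12)
    expect_equal(diag(fc), rep(1, nroi))
  }
  expect_equal(dim(pop$profiles$intensities), c(200, 17))
  # generators are pure functions of (parameters, seed)
  expect_identical(make_bundle(pop, subjects = 3, seed = 11), bundle)
})
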