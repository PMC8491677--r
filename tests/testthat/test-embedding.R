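test_that("row sparsification follows the interpolated-percentile rule", {
  m <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  out <- sparsify_rows(m, 75)               # 75th percentile = 3.25
  expect_equal(out, rbind(c(0, 0, 0, 4), c(4, 0, 0, 0)))
  expect_equal(sparsify_rows(m, 0), m)
  expect_warning(out <- sparsify_rows(rbind(c(5, 5, 5)), 75), "constant")
  expect_equal(out, rbind(c(5, 5, 5)))
  expect_error(sparsify_rows(m, 100), "\\[0,100\\)")
})

test_that("cosine affinity matches the loop-based oracle", {
  expect_equal(cosine_affinity(rbind(c(1, 0), c(0, 1)))$values[1, 2], 0)
  expect_equal(cosine_affinity(rbind(c(1, 2), c(2, 4)))$values[1, 2], 1)

  set.seed(3)
  m <- matrix(stats::runif(160), 8, 20)
  a <- cosine_affinity(m)$values
  for (i in 1:8) for (j in 1:8) {
    expect_equal(a[i, j],
                 if (i == j) 1 else
                   sum(m[i, ] * m[j, ]) / sqrt(sum(m[i, ]^2) * sum(m[j, ]^2)),
                 tolerance = 1e-12)
  }
  m[3, ] <- 0
  expect_error(cosine_affinity(m), "row 3")
})

test_that("normalized angle affinity maps angles to [0, 1]", {
  a <- normalized_angle_affinity(rbind(c(1, 0), c(0, 3), c(2, 0), c(-1, 0)))
  expect_equal(a$values[1, 2], 0.5, tolerance = 1e-12) # orthogonal
  expect_equal(a$values[1, 3], 1)                      # parallel
  expect_equal(a$values[1, 4], 0)                      # antiparallel
  expect_true(all(a$values >= 0 & a$values <= 1))
})

test_that("diffusion map matches the dense transition-matrix oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    A <- random_affinity(n)
    k <- 5
    got <- diffusion_map(A, k = k)
    want <- oracle_diffusion_map(A, k)
    expect_equal(got$eigenvalues_all, want$eigenvalues, tolerance = 1e-8)
    for (c in seq_len(k)) {
      expect_equal(abs(got$components[, c]), abs(want$components[, c]),
                   tolerance = 1e-6)
    }
  }
})

test_that("diffusion map handles degenerate and disconnected affinities", {
  # complete graph with equal weights: all nontrivial eigenvalues 0
  A <- matrix(1, 8, 8)
  g <- diffusion_map(A, k = 3)
  expect_equal(g$eigenvalues, rep(0, 3), tolerance = 1e-12)
  expect_equal(g$components, matrix(0, 8, 3), tolerance = 1e-10)

  # two cliques joined by one weak bridge: G1 separates them
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1
  A[6:10, 6:10] <- 1
  A[5, 6] <- A[6, 5] <- 0.01
  diag(A) <- 1
  g <- diffusion_map(A, k = 2)
  expect_true(all(sign(g$components[1:5, 1]) == sign(g$components[1, 1])))
  expect_true(all(sign(g$components[6:10, 1]) == -sign(g$components[1, 1])))

  # fully disconnected blocks are rejected
  A[5, 6] <- A[6, 5] <- 0
  expect_error(diffusion_map(A, k = 2), "disconnected")
  expect_error(diffusion_map(matrix(1, 5, 5), k = 5), "n - 1")
})

test_that("fixed diffusion time scales components by lambda^t", {
  A <- random_affinity(20)
  auto <- diffusion_map(A, k = 3)
  fixed <- diffusion_map(A, k = 3, diffusion_time = 2)
  lam <- auto$eigenvalues
  expect_equal(fixed$components,
               auto$components * rep((1 - lam) * lam, each = 20),
               tolerance = 1e-10)
  expect_equal(fixed$diffusion_time_mode, 2)
  expect_equal(auto$diffusion_time_mode, "automated")
})

test_that("variance explained normalizes the positive spectrum", {
  expect_equal(variance_explained(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(variance_explained(5), 1)
  ve <- variance_explained(c(3, 2, 1.5, 0.1))
  expect_true(all(diff(ve) <= 0))
  expect_equal(sum(ve), 1)
})

test_that("Procrustes alignment recovers planted rotations", {
  set.seed(4)
  src <- matrix(stats::rnorm(60), 20, 3)
  same <- procrustes_align(src, src)
  expect_equal(same$rotation, diag(3), tolerance = 1e-10)
  expect_equal(same$aligned, src, tolerance = 1e-10)

  flipped <- src %*% diag(c(1, -1, 1))
  pa <- procrustes_align(flipped, src)
  expect_equal(pa$rotation, diag(c(1, -1, 1)), tolerance = 1e-10)
  rep1 <- alignment_report(list(pa$rotation))
  expect_equal(unname(rep1$percentiles), rep(1, 3), tolerance = 1e-10)

  for (s in 1:5) {
    R0 <- random_orthogonal(3, seed = s)
    pa <- procrustes_align(src %*% R0, src)
    expect_equal(pa$aligned, src, tolerance = 1e-8)
    expect_equal(pa$rotation %*% R0, diag(3), tolerance = 1e-8)
    expect_equal(crossprod(pa$rotation), diag(3), tolerance = 1e-10)
  }
})

test_that("eccentricity is the rotation-invariant manifold norm", {
  expect_equal(eccentricity(rbind(c(0, 0, 0), c(3, 4, 0))), c(0, 5))
  set.seed(5)
  g <- matrix(stats::rnorm(90), 30, 3)
  for (s in 1:3) {
    expect_equal(eccentricity(g %*% random_orthogonal(3, seed = s)),
                 eccentricity(g), tolerance = 1e-10)
  }
  # Procrustes alignment never changes eccentricity
  ref <- matrix(stats::rnorm(90), 30, 3)
  expect_equal(eccentricity(procrustes_align(g, ref)$aligned),
               eccentricity(g), tolerance = 1e-10)
})

test_that("eccentricity is stable in the number of retained gradients", {
  mesh <- make_mesh(2, 0.5, seed = 6)
  ax <- plant_axes(mesh, seed = 7)
  cn <- make_connectome(ax, noise_sd = 0.1, seed = 8)
  g <- connectome_gradients(cn, k = 10)
  e3 <- eccentricity(g, k = 3)
  for (k in 4:10) {
    expect_gt(stats::cor(e3, eccentricity(g, k = k)), 0.99)
  }
})

test_that("embedding recovers planted axes, degrading with noise", {
  mesh <- make_mesh(2, 0.5, seed = 1)
  ax <- plant_axes(mesh, k = 3, smoothness = 2, seed = 2)
  ccs <- vapply(c(0, 0.1, 0.3), function(ns) {
    cn <- make_connectome(ax, noise_sd = ns, seed = 3)
    g <- connectome_gradients(cn, k = 3)
    mean(stats::cancor(g$components, ax$coords)$cor)
  }, numeric(1))
  expect_gt(min(stats::cancor(
    connectome_gradients(make_connectome(ax, noise_sd = 0, seed = 3),
                         k = 3)$components, ax$coords)$cor), 0.95)
  expect_gt(ccs[1], ccs[3])
  expect_gt(ccs[2], ccs[3])
})
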