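# Small meshes and independent oracles used across the suite. All fixtures
# are built in code; nothing is read from disk.

# single triangle, unit-ish edges
tri_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3)))
}

# 4-vertex "path-like" mesh: 1-2-3 collinear chain plus an apex; the direct
# 1-3 edge does not exist, so the 1->3 geodesic runs through vertex 2
chain_mesh <- function(edge_len = 1) {
  surface_mesh(
    rbind(c(0, 0, 0), c(edge_len, 0, 0), c(2 * edge_len, 0, 0),
          c(edge_len, 3 * edge_len, 0)),
    rbind(c(1, 2, 4), c(2, 3, 4))
  )
}

# planar triangulated grid, nx x ny vertices (for exhaustive oracles)
grid_mesh <- function(nx, ny, jitter = 0, seed = 1) {
  set.seed(seed)
  n <- nx * ny
  xy <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  v <- cbind(xy$x + stats::runif(n, -jitter, jitter),
             xy$y + stats::runif(n, -jitter, jitter), 0)
  id <- function(i, j) (j - 1) * nx + i
  tris <- NULL
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      tris <- rbind(tris,
                    c(id(i, j), id(i + 1, j), id(i, j + 1)),
                    c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
    }
  }
  surface_mesh(v, tris)
}

# brute-force all-pairs shortest paths (Floyd-Warshall) on the mesh edges
brute_force_geodesics <- function(mesh) {
  ed <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_len(nrow(ed$edges))) {
    i <- ed$edges[e, 1]; j <- ed$edges[e, 2]
    d[i, j] <- d[j, i] <- min(d[i, j], ed$lengths[e])
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

# step-up FDR by the textbook definition, written independently of p.adjust
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i, 1)
    adj[o[i]] <- prev
  }
  adj
}

# Cohen's kappa via the confusion-matrix closed form, loop-based
brute_force_kappa <- function(a, b) {
  lev <- union(unique(as.character(a)), unique(as.character(b)))
  k <- length(lev)
  conf <- matrix(0, k, k, dimnames = list(lev, lev))
  for (i in seq_along(a)) {
    conf[as.character(a[i]), as.character(b[i])] <-
      conf[as.character(a[i]), as.character(b[i])] + 1
  }
  n <- length(a)
  po <- sum(diag(conf)) / n
  pe <- 0
  for (l in lev) pe <- pe + sum(conf[l, ]) * sum(conf[, l]) / n^2
  (po - pe) / (1 - pe)
}

# dense diffusion-map oracle: eigendecompose the transition matrix P
# directly with the general (nonsymmetric) solver
oracle_diffusion_map <- function(A, k, alpha = 0.5) {
  d <- rowSums(A)
  L <- A / outer(d^alpha, d^alpha)
  P <- L / rowSums(L)
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord][-1]
  vecs <- Re(e$vectors)[, ord, drop = FALSE][, -1, drop = FALSE]
  vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), "/")
  comps <- sweep(vecs[, seq_len(k), drop = FALSE], 2,
                 vals[seq_len(k)] / (1 - vals[seq_len(k)]), "*")
  list(eigenvalues = vals, components = comps)
}

# random connected symmetric nonnegative affinity with unit diagonal
random_affinity <- function(n, density = 0.6) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  vals <- stats::runif(sum(up))
  vals[stats::runif(sum(up)) > density] <- 0
  A[up] <- vals
  A <- A + t(A)
  # ring to guarantee connectivity
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (A[i, j] == 0) A[i, j] <- A[j, i] <- stats::runif(1, 0.1, 1)
  }
  diag(A) <- 1
  A
}

# absolute correlation between two gradient columns (sign is arbitrary)
abs_cor <- function(a, b) abs(stats::cor(a, b))

# small default-structure population shared by integration-style tests
small_population <- function(seed = 42) {
  make_population(subdivisions = 2, roi_fraction = 0.5, seed = seed)
}

random_orthogonal <- function(k, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
}
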