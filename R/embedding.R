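# Affinity construction and diffusion map embedding: the manifold core.
#
# A row of the connectome is a vertex's connectivity profile. Rows are
# sparsified (keeping each row's strongest connections), converted to a
# symmetric affinity with a cosine or normalized-angle kernel, and embedded
# with an anisotropically normalized (alpha = 0.5) diffusion map. The
# resulting eigenvector columns are the connectivity gradients; their
# three-column Euclidean norm is the manifold eccentricity.

# deterministic eigenvector orientation: largest-|entry| coordinate positive
fix_column_signs <- function(m) {
  if (ncol(m) == 0L) return(m)
  s <- apply(m, 2L, function(v) {
    i <- which.max(abs(v))
    if (v[i] < 0) -1 else 1
  })
  sweep(m, 2L, s, "*")
}

#' Row-wise sparsification at a percentile
#'
#' Per row, entries strictly below that row's `percentile` value (linear
#' interpolation between order statistics, the default quantile rule) are set
#' to zero; survivors are unchanged. A constant row survives whole (inclusive
#' rule) with a warning.
#'
#' @param m numeric matrix, rows are profiles.
#' @param percentile percentile in `[0, 100)`.
#' @return sparsified matrix of the same shape.
#' @export
sparsify_rows <- function(m, percentile = 75) {
  if (percentile < 0 || percentile >= 100) stop("percentile must be in [0,100)")
  m <- as.matrix(m)
  thr <- apply(m, 1L, stats::quantile, probs = percentile / 100, names = FALSE)
  if (any(apply(m, 1L, function(r) max(r) == min(r)))) {
    warning("constant row(s): entire row survives sparsification")
  }
  m * (m >= thr)
}

row_normalize_l2 <- function(m, context) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop(context, ": all-zero profile at row ", which(nrm == 0)[1L])
  }
  m / nrm
}

new_affinity <- function(values, kernel, sparsity = NA_real_) {
  values <- (values + t(values)) / 2
  diag(values) <- 1
  structure(list(values = values, kernel_tag = kernel,
                 sparsity_percentile = sparsity),
            class = "affinity_matrix")
}

#' Cosine similarity affinity between row profiles
#'
#' `A_ij = <r_i, r_j> / (||r_i|| ||r_j||)`; symmetric with unit diagonal.
#'
#' @param m nonnegative matrix, rows are connectivity profiles.
#' @return an `affinity_matrix`.
#' @export
cosine_affinity <- function(m) {
  mn <- row_normalize_l2(as.matrix(m), "cosine_affinity")
  new_affinity(tcrossprod(mn), "cosine")
}

#' Normalized-angle affinity between row profiles
#'
#' `A_ij = 1 - arccos(cos_ij) / pi`, mapping parallel rows to 1, orthogonal
#' rows to 1/2, antiparallel rows to 0. Defined for profiles with negative
#' entries (e.g. microstructural profile covariance).
#'
#' @inheritParams cosine_affinity
#' @return an `affinity_matrix`.
#' @export
normalized_angle_affinity <- function(m) {
  mn <- row_normalize_l2(as.matrix(m), "normalized_angle_affinity")
  cosv <- pmin(pmax(tcrossprod(mn), -1), 1)
  new_affinity(1 - acos(cosv) / pi, "normalized_angle")
}

#' Diffusion map embedding of an affinity matrix
#'
#' Anisotropic normalization `L = D^-alpha A D^-alpha` followed by
#' row-normalization to the transition matrix `P = D_L^-1 L`, eigendecomposed
#' through its symmetric conjugate. The trivial eigenpair (eigenvalue 1,
#' constant eigenvector) is discarded. Under automated diffusion time
#' (`diffusion_time = NULL`, the convention of diffusion-time integration
#' over all scales) component `c` is scaled by `lambda_c / (1 - lambda_c)`;
#' with a fixed time `t`, by `lambda_c^t`. Eigenvector signs are fixed so
#' each component's largest-magnitude entry is positive.
#'
#' @param a an `affinity_matrix` or plain symmetric nonnegative matrix.
#' @param k number of components to retain (<= n - 1).
#' @param alpha anisotropic normalization exponent (0.5 balances geometry
#'   against sampling density).
#' @param diffusion_time `NULL` for automated scaling, or a fixed positive t.
#' @return object of class `gradient_set`: `components` (n x k),
#'   `eigenvalues` (the retained nontrivial eigenvalues, nonincreasing),
#'   `eigenvalues_all`, `alpha`, `diffusion_time_mode`, `kernel_tag`.
#' @export
diffusion_map <- function(a, k = 3, alpha = 0.5, diffusion_time = NULL) {
  A <- if (inherits(a, "affinity_matrix")) a$values else as.matrix(a)
  n <- nrow(A)
  if (k > n - 1L) stop("k must be <= n - 1")
  if (max(abs(A - t(A))) > 1e-10) stop("affinity must be symmetric")
  if (any(A < 0)) stop("affinity must be nonnegative")
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  )
  if (comp$no > 1L) stop("affinity graph is disconnected")

  d <- rowSums(A)
  L <- A / outer(d^alpha, d^alpha)
  dL <- rowSums(L)
  M <- L / outer(sqrt(dL), sqrt(dL))       # symmetric conjugate of P
  e <- eigen(M, symmetric = TRUE)
  lambdas <- e$values[-1L]
  if (any(lambdas >= 1 - 1e-12)) {
    stop("affinity numerically disconnected (nontrivial eigenvalue ~ 1)")
  }
  # eigenvectors of P = D_L^-1 L recovered from the symmetric problem
  psi <- e$vectors[, -1L, drop = FALSE] / sqrt(dL)
  psi <- sweep(psi, 2L, sqrt(colSums(psi^2)), "/")
  psi <- fix_column_signs(psi)
  scale_fac <- if (is.null(diffusion_time)) {
    lambdas / (1 - lambdas)
  } else {
    lambdas^diffusion_time
  }
  comps <- sweep(psi[, seq_len(k), drop = FALSE], 2L,
                 scale_fac[seq_len(k)], "*")
  structure(
    list(components = comps,
         eigenvalues = lambdas[seq_len(k)],
         eigenvalues_all = lambdas,
         alpha = alpha,
         diffusion_time_mode = if (is.null(diffusion_time)) "automated"
                               else diffusion_time,
         kernel_tag = if (inherits(a, "affinity_matrix")) a$kernel_tag
                      else "custom"),
    class = "gradient_set"
  )
}

#' @export
print.gradient_set <- function(x, ...) {
  ve <- variance_explained(x$eigenvalues_all)
  cat(sprintf(
    "gradient_set: %d vertices x %d components (alpha = %g, time = %s)\n",
    nrow(x$components), ncol(x$components), x$alpha,
    as.character(x$diffusion_time_mode)))
  cat(sprintf("  variance explained by retained components: %.1f%%\n",
              100 * sum(ve[seq_len(ncol(x$components))])))
  invisible(x)
}

#' Fraction of variance explained per component
#'
#' `fraction_c = lambda_c / sum(lambda)` over the supplied nontrivial
#' eigenvalues (negative eigenvalues, if any, are excluded from the sum).
#'
#' @param eigenvalues nonincreasing eigenvalues, or a `gradient_set` (its
#'   full nontrivial spectrum is used).
#' @return fractions summing to 1 over the positive spectrum.
#' @export
variance_explained <- function(eigenvalues) {
  if (inherits(eigenvalues, "gradient_set")) {
    eigenvalues <- eigenvalues$eigenvalues_all
  }
  pos <- pmax(eigenvalues, 0)
  pos / sum(pos)
}

#' Procrustes alignment of gradient components to a reference
#'
#' Finds the orthogonal matrix `R` minimizing `||source R - reference||_F`
#' via the singular value decomposition of `source' reference` (`R = U V'`).
#' No scaling or translation: eigenvector bases differ across subjects or
#' hemispheres only by rotation/reflection and sign, which is exactly what an
#' orthogonal map absorbs. Orthogonal alignment preserves row norms, so
#' manifold eccentricity is invariant under it.
#'
#' @param source matrix (or `gradient_set`) to align.
#' @param reference matrix (or `gradient_set`) of identical shape.
#' @return list with `aligned` (source x rotation) and `rotation` (k x k
#'   orthogonal).
#' @export
procrustes_align <- function(source, reference) {
  S <- if (inherits(source, "gradient_set")) source$components else as.matrix(source)
  R0 <- if (inherits(reference, "gradient_set")) reference$components else as.matrix(reference)
  if (!all(dim(S) == dim(R0))) stop("source and reference must share a shape")
  sv <- svd(crossprod(S, R0))
  if (min(sv$d) < 1e-12 * max(sv$d)) {
    warning("rank-deficient cross-product; alignment uses the SVD solution")
  }
  rot <- sv$u %*% t(sv$v)
  list(aligned = S %*% rot, rotation = rot)
}

#' Rotation diagnostics across a set of Procrustes alignments
#'
#' Summarizes how far each aligned set was rotated: the 5th/50th/95th
#' percentiles of the sign-adjusted diagonal elements of the rotation
#' matrices (each diagonal element multiplied by its own sign, since gradient
#' signs are arbitrary). Values near 1 indicate near-identity rotations.
#'
#' @param rotations list of k x k orthogonal matrices.
#' @return object of class `alignment_report`: list with `percentiles`
#'   (named: p5, p50, p95) and `diagonals` (sets x k).
#' @export
alignment_report <- function(rotations) {
  diags <- t(vapply(rotations, function(r) {
    d <- diag(r)
    d * sign(d)
  }, numeric(ncol(rotations[[1L]]))))
  q <- stats::quantile(diags, probs = c(0.05, 0.5, 0.95), names = FALSE)
  structure(list(percentiles = c(p5 = q[1L], p50 = q[2L], p95 = q[3L]),
                 diagonals = diags),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf(
    "alignment_report: sign-adjusted rotation diagonals p5/p50/p95 = %.3f/%.3f/%.3f\n",
    x$percentiles["p5"], x$percentiles["p50"], x$percentiles["p95"]))
  invisible(x)
}

#' Manifold eccentricity
#'
#' Per-vertex Euclidean distance to the origin of the space spanned by the
#' supplied gradient columns (conventionally the first three). High values
#' mark vertices with strongly differentiated connectivity profiles.
#'
#' @param components n x k matrix of gradient columns, or a `gradient_set`.
#' @param k number of leading columns to use (default: all supplied).
#' @return nonnegative per-vertex map.
#' @export
eccentricity <- function(components, k = NULL) {
  m <- if (inherits(components, "gradient_set")) components$components
       else as.matrix(components)
  if (!is.null(k)) m <- m[, seq_len(k), drop = FALSE]
  sqrt(rowSums(m^2))
}
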