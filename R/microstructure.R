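# Microstructural profile covariance (MPC): parcel-by-parcel partial
# correlations of cortical depth-wise intensity profiles, controlling for
# the cortex-wide mean profile, and the diffusion-map gradient of the
# resulting matrix. The pipeline order is fixed: axis-trend correction ->
# parcellation -> MPC -> gradient.

#' Construct a depth-profile set
#'
#' @param intensities parcels (or vertices) x depth-samples matrix of
#'   staining/relaxometry intensities (arbitrary units). Profiles are
#'   consumed as given; if the deepest sample was removed upstream (a common
#'   partial-volume precaution), `depth_count` simply records what remains.
#' @param axis_coordinate optional per-parcel scalar (e.g.
#'   anterior-posterior position in mm) for trend correction.
#' @param planted_axis optional ground-truth axis (synthetic data only).
#' @return object of class `profile_set`.
#' @export
profile_set <- function(intensities, axis_coordinate = NULL,
                        planted_axis = NULL) {
  intensities <- as.matrix(intensities)
  if (anyNA(intensities)) stop("intensities contain missing values")
  if (ncol(intensities) < 3L) stop("need at least 3 depth samples")
  if (!is.null(axis_coordinate) &&
      length(axis_coordinate) != nrow(intensities)) {
    stop("axis_coordinate length must equal parcel count")
  }
  structure(list(intensities = intensities, depth_count = ncol(intensities),
                 axis_coordinate = axis_coordinate,
                 planted_axis = planted_axis),
            class = "profile_set")
}

#' Remove a linear along-axis intensity trend from profiles
#'
#' Per depth, intensities are replaced by the residuals of a simple linear
#' regression on `axis_coordinate` plus that depth's grand mean (so scanner-
#' or staining-related anterior-posterior drifts do not masquerade as
#' microstructural covariance).
#'
#' @param p a `profile_set` with `axis_coordinate` present.
#' @return a `profile_set` with residualized intensities.
#' @export
correct_axis_trend <- function(p) {
  ax <- p$axis_coordinate
  if (is.null(ax)) stop("axis_coordinate is required for trend correction")
  if (stats::sd(ax) == 0) stop("axis_coordinate is constant")
  Y <- p$intensities
  X <- cbind(1, ax)
  beta <- solve(crossprod(X), crossprod(X, Y))
  resid <- Y - X %*% beta
  out <- p
  out$intensities <- resid +
    matrix(colMeans(Y), nrow(Y), ncol(Y), byrow = TRUE)
  out
}

#' Average per-vertex data within parcels
#'
#' Unweighted mean within each parcel; parcels ordered by ascending label.
#'
#' @param values numeric vector or vertices x k matrix.
#' @param labels per-vertex parcel labels (factor or coercible).
#' @return per-parcel means (vector or parcels x k matrix, rownames =
#'   labels).
#' @export
parcellate <- function(values, labels) {
  labels <- as.factor(labels)
  empty <- levels(labels)[tabulate(labels, nbins = nlevels(labels)) == 0L]
  if (length(empty) > 0L) stop("empty parcel: ", empty[1L])
  mat <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  if (nrow(mat) != length(labels)) stop("values do not match labels")
  sums <- rowsum(mat, labels)
  out <- sums / as.vector(table(labels))
  if (!is.matrix(values)) drop(out) else out
}

#' Microstructural profile covariance matrix
#'
#' Partial Pearson correlation of every profile pair across depths,
#' controlling for the mean profile over all parcels:
#' `partial_ij = (r_ij - r_ic r_jc) / sqrt((1 - r_ic^2)(1 - r_jc^2))`.
#' Algebraically identical to correlating the residuals of each profile
#' after regressing out the mean profile. Scale-free: invariant to per-
#' parcel affine rescaling. Entries for profiles collinear with the mean
#' profile (`|r_ic| = 1`) are flagged `NA` with a warning. Diagonal set
#' to 1 by convention; negative partial correlations are retained (the
#' normalized-angle kernel downstream is defined for them).
#'
#' @param p a `profile_set` (>= 3 depths, profiles non-constant).
#' @return object of class `mpc_matrix`: list with `values` (parcels x
#'   parcels) and `controlled_profile` (the mean profile).
#' @export
mpc_matrix <- function(p) {
  Y <- p$intensities
  if (nrow(unique(Y)) == 1L) stop("all profiles identical; MPC undefined")
  sds <- apply(Y, 1L, stats::sd)
  if (any(sds == 0)) stop("constant profile at parcel ", which(sds == 0)[1L])
  ctrl <- colMeans(Y)
  r <- stats::cor(t(Y))
  rc <- drop(stats::cor(t(Y), ctrl))
  denom2 <- 1 - rc^2
  collinear <- denom2 <= 1e-12
  denom2[collinear] <- NA_real_
  partial <- (r - outer(rc, rc)) / sqrt(outer(denom2, denom2))
  if (any(collinear)) {
    warning(sum(collinear),
            " profile(s) collinear with the mean profile; entries set NA")
  }
  partial <- (partial + t(partial)) / 2
  diag(partial) <- 1
  structure(list(values = partial, controlled_profile = ctrl),
            class = "mpc_matrix")
}

#' Gradient of a microstructural profile covariance matrix
#'
#' Row-wise sparsification at the `sparsity` percentile (default 90: only
#' each parcel's strongest 10% of couplings survive), normalized-angle
#' affinity, then diffusion map embedding with `alpha = 0.5` and automated
#' diffusion time. Negative MPC entries are retained before sparsification
#' unless `zero_negative`.
#'
#' @param m an `mpc_matrix`.
#' @param k number of gradients.
#' @param sparsity row-sparsity percentile.
#' @param zero_negative zero out negative MPC values first (the common
#'   alternative convention).
#' @return a `gradient_set` (carries `sparsity` and kernel metadata).
#' @export
mpc_gradient <- function(m, k = 3, sparsity = 90, zero_negative = FALSE) {
  v <- m$values
  if (anyNA(v)) stop("MPC matrix contains flagged (NA) entries")
  if (zero_negative) v[v < 0] <- 0
  s <- sparsify_rows(v, percentile = sparsity)
  g <- diffusion_map(normalized_angle_affinity(s), k = k, alpha = 0.5)
  g$sparsity_percentile <- sparsity
  g
}
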