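# Vertex-wise structural connectome construction from weighted streamline
# endpoint records, and its nodal summaries.

#' Streamline endpoint records
#'
#' Two 3D termini plus a positive weight per streamline (e.g. a SIFT2
#' cross-section multiplier).
#'
#' @param termini_a,termini_b n x 3 coordinate matrices in mm.
#' @param weight positive weight per streamline.
#' @return object of class `endpoint_set`.
#' @export
endpoint_set <- function(termini_a, termini_b, weight) {
  termini_a <- as.matrix(termini_a)
  termini_b <- as.matrix(termini_b)
  weight <- as.numeric(weight)
  if (ncol(termini_a) != 3L || ncol(termini_b) != 3L) {
    stop("termini must be n x 3 matrices")
  }
  if (nrow(termini_a) != nrow(termini_b) ||
      nrow(termini_a) != length(weight)) {
    stop("termini and weight lengths disagree")
  }
  if (any(!is.finite(termini_a)) || any(!is.finite(termini_b))) {
    stop("termini must be finite")
  }
  if (any(weight <= 0)) stop("weights must be positive")
  structure(list(termini_a = termini_a, termini_b = termini_b,
                 weight = weight),
            class = "endpoint_set")
}

new_connectome <- function(weights, seed_ids, target_ids, smoothed = FALSE) {
  structure(list(weights = weights, seed_ids = as.integer(seed_ids),
                 target_ids = as.integer(target_ids),
                 smoothed_flag = smoothed),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d seeds x %d targets, total weight %.4g%s\n",
              nrow(x$weights), ncol(x$weights), sum(x$weights),
              if (x$smoothed_flag) " (smoothed)" else ""))
  invisible(x)
}

nearest_vertex <- function(points, vertices) {
  # n_points x n_vertices squared distances, computed blockwise
  vn2 <- rowSums(vertices^2)
  d2 <- outer(rowSums(points^2), vn2, "+") - 2 * tcrossprod(points, vertices)
  d2[d2 < 0] <- 0
  idx <- max.col(-d2, ties.method = "first")
  list(index = idx, dist = sqrt(d2[cbind(seq_len(nrow(points)), idx)]))
}

#' Assign streamline termini to surface vertices
#'
#' Each terminus is mapped to its Euclidean nearest vertex on its mesh. A
#' streamline contributes its weight to cell (nearest(a), nearest(b)) iff
#' both nearest-vertex distances are at most `max_dist_mm`; otherwise it is
#' discarded. Streamlines whose seed-side terminus maps to a vertex outside
#' the seed mesh's ROI are dropped and counted separately.
#'
#' @param endpoints an `endpoint_set` (terminus a is the seed side).
#' @param seed_mesh mesh whose ROI defines the connectome rows.
#' @param target_mesh mesh defining the connectome columns (may equal
#'   `seed_mesh`).
#' @param max_dist_mm discard radius (default 3 mm).
#' @return list with `connectome` (seed ROI vertices x target vertices),
#'   `n_discarded` (termini beyond `max_dist_mm`), `discarded_weight`,
#'   `n_out_of_roi`, `out_of_roi_weight`.
#' @export
assign_endpoints <- function(endpoints, seed_mesh, target_mesh = seed_mesh,
                             max_dist_mm = 3) {
  if (max_dist_mm <= 0) stop("max_dist_mm must be positive")
  roi <- which(seed_mesh$roi_mask)
  n_targets <- nrow(target_mesh$vertices)
  if (length(endpoints$weight) == 0L) {
    warning("empty endpoint set; returning an empty connectome")
    return(list(connectome = new_connectome(
                  matrix(0, length(roi), n_targets), roi, seq_len(n_targets)),
                n_discarded = 0L, discarded_weight = 0,
                n_out_of_roi = 0L, out_of_roi_weight = 0))
  }
  na <- nearest_vertex(endpoints$termini_a, seed_mesh$vertices)
  nb <- nearest_vertex(endpoints$termini_b, target_mesh$vertices)
  too_far <- na$dist > max_dist_mm | nb$dist > max_dist_mm
  out_roi <- !too_far & !seed_mesh$roi_mask[na$index]
  keep <- !too_far & !out_roi
  w <- matrix(0, length(roi), n_targets)
  if (any(keep)) {
    row_of <- integer(nrow(seed_mesh$vertices))
    row_of[roi] <- seq_along(roi)
    cell <- (nb$index[keep] - 1L) * length(roi) + row_of[na$index[keep]]
    acc <- rowsum(endpoints$weight[keep], cell)
    w[as.integer(rownames(acc))] <- acc[, 1L]
  }
  list(connectome = new_connectome(w, roi, seq_len(n_targets)),
       n_discarded = sum(too_far),
       discarded_weight = sum(endpoints$weight[too_far]),
       n_out_of_roi = sum(out_roi),
       out_of_roi_weight = sum(endpoints$weight[out_roi]))
}

#' Smooth a connectome on the surface
#'
#' Applies geodesic Gaussian smoothing along the seed-vertex axis (rows) by
#' default, optionally along both axes when the targets also live on the
#' seed mesh ROI.
#'
#' @param c a `connectome` whose seeds are the mesh ROI.
#' @param mesh the seed `surface_mesh`.
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @param axes `"seed"` or `"both"`.
#' @return smoothed `connectome` with `smoothed_flag = TRUE`.
#' @export
smooth_connectome <- function(c, mesh, fwhm_mm = 20, axes = c("seed", "both")) {
  axes <- match.arg(axes)
  K <- smoothing_kernel(mesh, fwhm_mm)
  w <- crossprod(K, c$weights)
  if (axes == "both") {
    if (ncol(w) != nrow(K)) {
      stop("target axis does not match the mesh ROI; cannot smooth both axes")
    }
    w <- w %*% K
  }
  out <- c
  out$weights <- w
  out$smoothed_flag <- TRUE
  out
}

#' Degree centrality of a connectome
#'
#' Sum of each node's connection weights (column sums for targets of a
#' seed x target matrix; row sums give the seed-side degree).
#'
#' @param c a `connectome` or nonnegative matrix.
#' @param margin 1 for seed-side (row) sums, 2 for target-side (column) sums.
#' @return nonnegative per-node map.
#' @export
degree_centrality <- function(c, margin = 1L) {
  w <- if (inherits(c, "connectome")) c$weights else as.matrix(c)
  if (margin == 1L) rowSums(w) else colSums(w)
}

#' Connectivity distance
#'
#' A per-seed-node proxy for the prevalence of long-range connections:
#' threshold the connectivity matrix at its `percentile` (matrix-wide over
#' nonzero entries by default, inclusive at the threshold), then average the
#' geodesic distances of each node's surviving connections (unweighted).
#' Invariant to rescaling all weights by a positive constant.
#'
#' @param c a `connectome`.
#' @param geo a `geodesic_matrix` covering the seed x target pairs.
#' @param percentile threshold percentile (default 80).
#' @param domain `"nonzero"` (percentile over nonzero entries; vertex-wise
#'   connectomes are dominated by structural zeros) or `"all"`.
#' @return per-seed map in mm; `NA` (with a warning) for nodes with no
#'   surviving connection.
#' @export
connectivity_distance <- function(c, geo, percentile = 80,
                                  domain = c("nonzero", "all")) {
  domain <- match.arg(domain)
  w <- c$weights
  d <- geo$distances
  if (!all(dim(d) == dim(w))) stop("geodesic matrix does not cover connectome")
  vals <- if (domain == "nonzero") w[w > 0] else as.vector(w)
  if (length(vals) == 0L) stop("connectome has no nonzero weights")
  thr <- stats::quantile(vals, probs = percentile / 100, names = FALSE)
  surv <- w >= thr & w > 0
  out <- vapply(seq_len(nrow(w)), function(i) {
    s <- surv[i, ]
    if (!any(s)) NA_real_ else mean(d[i, s])
  }, numeric(1L))
  if (anyNA(out)) {
    warning(sum(is.na(out)), " node(s) with no surviving connection (NA)")
  }
  out
}

#' Mean connectivity profile of the extreme decile of a score
#'
#' Selects the `ceiling(fraction * n)` seed vertices with the highest
#' (`tail = "top"`) or lowest (`"bottom"`) score and returns the unweighted
#' mean of their connectome rows. Ties in the score are broken by vertex
#' index (stable order).
#'
#' @param c a `connectome`.
#' @param score per-seed numeric map.
#' @param tail `"top"` or `"bottom"`.
#' @param fraction fraction of seeds to select, in (0, 0.5].
#' @return mean target-connectivity profile (length = n targets).
#' @export
extreme_decile_profile <- function(c, score, tail = c("top", "bottom"),
                                   fraction = 0.10) {
  tail <- match.arg(tail)
  w <- c$weights
  if (length(score) != nrow(w)) stop("score length must equal seed count")
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  n_sel <- ceiling(fraction * nrow(w))
  ord <- order(if (tail == "top") -score else score, seq_along(score))
  colMeans(w[ord[seq_len(n_sel)], , drop = FALSE])
}
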