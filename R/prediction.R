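# Gradient-based prediction of functional organization: multinomial
# logistic classification of network labels from the first three gradients
# (evaluated with Cohen's kappa), and best-first CART regression of
# edgewise functional connectivity from gradient-space distances.

#' Split subjects into k folds
#'
#' Seeded shuffle followed by contiguous chunking into folds of as-equal-as-
#' possible size (the first `n %% k` folds get one extra subject).
#'
#' @param subjects vector of subject identifiers.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return object of class `fold_plan`: list with `folds` (list of id
#'   vectors) and `k`.
#' @export
kfold_split <- function(subjects, k = 5, seed = 1) {
  if (k < 2L) stop("k must be >= 2")
  n <- length(subjects)
  if (k > n) stop("more folds than subjects")
  set.seed(seed)
  shuffled <- subjects[sample.int(n)]
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(i) shuffled[starts[i]:ends[i]])
  structure(list(folds = folds, k = k), class = "fold_plan")
}

#' Fit a multinomial logistic network classifier on gradients
#'
#' Maximum-likelihood multinomial logistic regression (softmax over linear
#' scores, first label level as reference category with coefficients fixed
#' at zero), with a tiny ridge penalty (1e-8) solely to keep coefficients
#' finite under perfect separation.
#'
#' @param gradients vertices x n_gradients predictor matrix (typically the
#'   first three gradients).
#' @param labels per-vertex network labels (factor; >= 2 levels, each with
#'   >= 10 vertices).
#' @return object of class `network_model`: list with `beta`
#'   ((1 + n_gradients) x n_networks, reference column zero) and `classes`.
#' @export
fit_network_classifier <- function(gradients, labels) {
  gradients <- as.matrix(gradients)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 networks")
  if (any(table(labels) < 10L)) {
    stop("every network needs at least 10 vertices")
  }
  if (nrow(gradients) != length(labels)) stop("gradients do not match labels")
  df <- data.frame(.y = labels, gradients)
  fit <- nnet::multinom(.y ~ ., data = df, decay = 1e-8, trace = FALSE,
                        maxit = 500, MaxNWts = 5000)
  if (fit$convergence != 0) {
    warning("multinomial fit hit the iteration cap before convergence")
  }
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1L)   # 2-class case
  beta <- cbind(0, t(co))
  colnames(beta) <- levels(labels)
  rownames(beta) <- c("(Intercept)", colnames(gradients) %||%
                        paste0("G", seq_len(ncol(gradients))))
  structure(list(beta = beta, classes = levels(labels), ridge = 1e-8),
            class = "network_model")
}

#' Predict network labels from gradients
#'
#' Softmax probabilities from the model's linear scores; each vertex is
#' assigned the network with the highest probability, ties broken by class
#' order.
#'
#' @param model a `network_model`.
#' @param gradients vertices x n_gradients matrix.
#' @return list with `labels` (factor) and `probabilities` (vertices x
#'   networks, rows summing to 1).
#' @export
predict_networks <- function(model, gradients) {
  gradients <- as.matrix(gradients)
  scores <- cbind(1, gradients) %*% model$beta
  scores <- scores - apply(scores, 1L, max)
  probs <- exp(scores)
  probs <- probs / rowSums(probs)
  idx <- max.col(probs, ties.method = "first")
  list(labels = factor(model$classes[idx], levels = model$classes),
       probabilities = probs)
}

#' Cohen's kappa agreement between two labelings
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_e` from the marginal products.
#' If both labelings are the same constant, agreement is perfect and kappa
#' is defined as 1; different constants give an error (`p_e = 1`).
#'
#' @param a,b label vectors of equal length.
#' @return scalar in [-1, 1].
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  lev <- union(as.character(a), as.character(b))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe < .Machine$double.eps) {
    if (po == 1) return(1)
    stop("chance agreement is 1 with imperfect agreement; kappa undefined")
  }
  (po - pe) / (1 - pe)
}

#' Gradient-space distance features for vertex pairs
#'
#' Per pair, the Euclidean distance between the two vertices' gradient
#' coordinates; optionally augmented with per-axis absolute differences.
#'
#' @param gradients vertices x k matrix.
#' @param pairs m x 2 matrix of vertex index pairs.
#' @param per_axis add |g_a(i) - g_a(j)| columns per axis.
#' @return m x p feature matrix (first column: Euclidean distance).
#' @export
gradient_distance_features <- function(gradients, pairs, per_axis = FALSE) {
  gradients <- as.matrix(gradients)
  diffs <- gradients[pairs[, 1L], , drop = FALSE] -
    gradients[pairs[, 2L], , drop = FALSE]
  feat <- matrix(sqrt(rowSums(diffs^2)), ncol = 1L,
                 dimnames = list(NULL, "dist"))
  if (per_axis) {
    ax <- abs(diffs)
    colnames(ax) <- paste0("absdiff", seq_len(ncol(ax)))
    feat <- cbind(feat, ax)
  }
  feat
}

#' All within-ROI vertex pairs (i < j)
#'
#' @param n number of vertices.
#' @return (n(n-1)/2) x 2 index matrix.
#' @export
vertex_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(idx[, 1L], idx[, 2L])
}

# ---------------------------------------------------------------------------
# Best-first CART regression tree with a cap on the number of splits.

# best admissible split of y over one feature; returns NULL if none
best_split_feature <- function(x, y, min_leaf) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(y)
  cs <- cumsum(ys)
  cs2 <- cumsum(ys^2)
  i <- seq_len(n - 1L)
  valid <- i >= min_leaf & (n - i) >= min_leaf & xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)
  i <- i[valid]
  sse_l <- cs2[i] - cs[i]^2 / i
  sse_r <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  tot <- sse_l + sse_r
  thr <- (xs[i] + xs[i + 1L]) / 2
  best <- which(tot == min(tot))
  best <- best[which.min(thr[best])]          # tie-break: lowest threshold
  list(threshold = thr[best], sse_children = tot[best])
}

best_split_node <- function(features, y, idx, min_leaf) {
  yy <- y[idx]
  if (length(idx) < 2L * min_leaf) return(NULL)
  parent_sse <- sum((yy - mean(yy))^2)
  best <- NULL
  for (j in seq_len(ncol(features))) {
    cand <- best_split_feature(features[idx, j], yy, min_leaf)
    if (is.null(cand)) next
    gain <- parent_sse - cand$sse_children
    if (is.null(best) || gain > best$gain + 1e-12) {
      best <- list(feature = j, threshold = cand$threshold, gain = gain)
    }
  }
  if (is.null(best) || best$gain <= 1e-12) return(NULL)
  best
}

#' Fit a regression tree of FC on gradient-distance features
#'
#' Greedy best-first CART: at each step, split the leaf (and threshold)
#' giving the largest reduction in total squared error, subject to both
#' children holding at least `min_leaf` samples; growth stops at
#' `max_splits` internal nodes or when no admissible split improves the
#' fit. Leaf values are the means of their training responses. Ties are
#' broken deterministically (lowest feature index, lowest threshold,
#' earliest-created leaf). A constant response yields a single-leaf tree.
#'
#' @param features per-pair feature matrix (see
#'   [gradient_distance_features()]).
#' @param fc_values per-pair response vector.
#' @param min_leaf minimum samples per leaf (default 20).
#' @param max_splits maximum number of internal nodes (default 20).
#' @return object of class `tree_model`: list of `nodes` (each with
#'   `is_leaf`, `value`, `n`, and for internal nodes `feature`,
#'   `threshold`, `left`, `right`), plus `n_splits`, `min_leaf`,
#'   `max_splits`.
#' @export
fit_fc_tree <- function(features, fc_values, min_leaf = 20, max_splits = 20) {
  features <- as.matrix(features)
  y <- as.numeric(fc_values)
  n <- length(y)
  if (nrow(features) != n) stop("features do not match responses")
  if (n < 2L * min_leaf) stop("need at least 2 * min_leaf samples")

  nodes <- list(list(is_leaf = TRUE, value = mean(y), n = n,
                     idx = seq_len(n)))
  pending <- list(`1` = best_split_node(features, y, seq_len(n), min_leaf))
  n_splits <- 0L
  while (n_splits < max_splits) {
    gains <- vapply(pending, function(p) if (is.null(p)) -Inf else p$gain,
                    numeric(1L))
    if (length(gains) == 0L || max(gains) == -Inf) break
    leaf_id <- as.integer(names(pending)[which.max(gains)])
    sp <- pending[[as.character(leaf_id)]]
    pending[[as.character(leaf_id)]] <- NULL
    idx <- nodes[[leaf_id]]$idx
    go_left <- features[idx, sp$feature] < sp$threshold
    lid <- length(nodes) + 1L
    rid <- length(nodes) + 2L
    for (side in list(list(id = lid, idx = idx[go_left]),
                      list(id = rid, idx = idx[!go_left]))) {
      nodes[[side$id]] <- list(is_leaf = TRUE, value = mean(y[side$idx]),
                               n = length(side$idx), idx = side$idx)
      pending[[as.character(side$id)]] <-
        best_split_node(features, y, side$idx, min_leaf)
    }
    nodes[[leaf_id]] <- list(is_leaf = FALSE, feature = sp$feature,
                             threshold = sp$threshold, left = lid,
                             right = rid, n = length(idx),
                             value = nodes[[leaf_id]]$value)
    n_splits <- n_splits + 1L
  }
  nodes <- lapply(nodes, function(nd) { nd$idx <- NULL; nd })
  structure(list(nodes = nodes, n_splits = n_splits, min_leaf = min_leaf,
                 max_splits = max_splits),
            class = "tree_model")
}

#' Predict responses from a fitted regression tree
#'
#' @param model a `tree_model`.
#' @param features per-pair feature matrix.
#' @return numeric predictions.
#' @export
predict_fc_tree <- function(model, features) {
  features <- as.matrix(features)
  vapply(seq_len(nrow(features)), function(i) {
    id <- 1L
    nd <- model$nodes[[id]]
    while (!nd$is_leaf) {
      id <- if (features[i, nd$feature] < nd$threshold) nd$left else nd$right
      nd <- model$nodes[[id]]
    }
    nd$value
  }, numeric(1L))
}

#' Evaluate functional connectivity predictions
#'
#' Per-subject Pearson correlation between predicted and empirical edge
#' values over all pairs, and a per-vertex correlation over the pairs
#' incident to each vertex, pooled across subjects.
#'
#' @param predicted per-pair predictions: vector (shared across subjects)
#'   or pairs x subjects matrix.
#' @param empirical pairs x subjects matrix of empirical edge values.
#' @param pairs m x 2 vertex index pairs.
#' @param n_vertices number of vertices (default inferred from `pairs`).
#' @return list with `per_subject_r` and `per_vertex_r`.
#' @export
evaluate_fc_prediction <- function(predicted, empirical, pairs,
                                   n_vertices = max(pairs)) {
  empirical <- as.matrix(empirical)
  if (!is.matrix(predicted)) {
    predicted <- matrix(predicted, nrow(empirical), ncol(empirical))
  }
  if (!all(dim(predicted) == dim(empirical))) {
    stop("predicted and empirical shapes disagree")
  }
  per_subject <- vapply(seq_len(ncol(empirical)), function(s) {
    stats::cor(predicted[, s], empirical[, s])
  }, numeric(1L))
  per_vertex <- vapply(seq_len(n_vertices), function(v) {
    rows <- which(pairs[, 1L] == v | pairs[, 2L] == v)
    stats::cor(as.vector(predicted[rows, ]), as.vector(empirical[rows, ]))
  }, numeric(1L))
  list(per_subject_r = per_subject, per_vertex_r = per_vertex)
}
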