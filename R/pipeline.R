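# End-to-end orchestration of the synthetic study: simulate -> connectome
# summaries -> gradients -> spatially-corrected statistics -> MPC ->
# prediction. Every stage is a thin wrapper over the exported functions, so
# any stage can be re-run in isolation from the returned results and config.

#' Default pipeline configuration
#'
#' Stage parameters with the analysis defaults: 3 mm endpoint discard
#' radius, 20 mm FWHM surface smoothing, 75th-percentile row sparsity with a
#' cosine kernel and alpha = 0.5 for connectome gradients, 80th-percentile
#' threshold for connectivity distance, 1000 Moran surrogates, 90%
#' sparsity / normalized-angle kernel for the MPC gradient, and a
#' 5-fold x (min leaf 20, max splits 20) decision-tree protocol.
#'
#' @param seed global seed; every stochastic stage derives its seed from it.
#' @return named list of parameters.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    mesh_subdivisions = 2, roi_fraction = 0.5,
    n_axes = 3, smoothness = 2, n_networks = 4,
    n_parcels = 200, n_depths = 17,
    subjects = 75, conn_noise_sd = 0.1, fc_noise_sd = 0.1, fc_slope = 0.5,
    n_targets = 400,
    max_dist_mm = 3, fwhm_mm = 20, smooth = TRUE,
    sparsity = 75, kernel = "cosine", alpha = 0.5, n_components = 10,
    conn_dist_percentile = 80,
    n_surrogates = 1000, fdr_q = 0.05, weights_scheme = "inverse_distance",
    mpc_sparsity = 90,
    k_folds = 5, min_leaf = 20, max_splits = 20
  )
}

#' Connectome-to-gradients convenience wrapper
#'
#' Row sparsification, affinity kernel, diffusion map — the standard
#' gradient construction applied to one connectivity matrix.
#'
#' @param weights seeds x targets nonnegative matrix (or `connectome`).
#' @param sparsity row-sparsity percentile.
#' @param kernel `"cosine"` or `"normalized_angle"`.
#' @param k number of components.
#' @param alpha diffusion-map normalization exponent.
#' @return a `gradient_set`.
#' @export
connectome_gradients <- function(weights, sparsity = 75, kernel = "cosine",
                                 k = 10, alpha = 0.5) {
  w <- if (inherits(weights, "connectome")) weights$weights else as.matrix(weights)
  s <- sparsify_rows(w, percentile = sparsity)
  aff <- switch(kernel,
                cosine = cosine_affinity(s),
                normalized_angle = normalized_angle_affinity(s),
                stop("unknown kernel: ", kernel))
  g <- diffusion_map(aff, k = k, alpha = alpha)
  g$sparsity_percentile <- sparsity
  g
}

#' Subject gradients aligned to a common reference
#'
#' Embeds each subject connectome, aligns every subject to the first by
#' Procrustes, and returns the per-subject aligned components, the
#' group-level mean, and the rotation diagnostics.
#'
#' @param connectomes list of subject `connectome`s (or matrices).
#' @param mesh optional `surface_mesh`; when supplied with `fwhm_mm > 0`,
#'   connectomes are smoothed along the seed axis first.
#' @param k components to retain for alignment (default 3).
#' @param config pipeline parameter list (see [default_config()]).
#' @return list with `subject_gradients` (list of n x k), `group` (n x k
#'   mean of aligned), `report` (an `alignment_report`), `eigenvalues_all`
#'   (subject-mean spectrum), `gradient_sets` (first subject's, for
#'   metadata).
#' @export
group_gradients <- function(connectomes, mesh = NULL, k = 3,
                            config = default_config()) {
  embed_one <- function(cn) {
    w <- if (inherits(cn, "connectome")) cn else new_connectome(
      as.matrix(cn), seq_len(nrow(cn)), seq_len(ncol(cn)))
    if (!is.null(mesh) && isTRUE(config$smooth) && config$fwhm_mm > 0) {
      w <- smooth_connectome(w, mesh, fwhm_mm = config$fwhm_mm)
    }
    connectome_gradients(w, sparsity = config$sparsity,
                         kernel = config$kernel,
                         k = max(k, config$n_components),
                         alpha = config$alpha)
  }
  gsets <- lapply(connectomes, embed_one)
  ref <- gsets[[1L]]$components[, seq_len(k), drop = FALSE]
  aligned <- vector("list", length(gsets))
  rotations <- vector("list", length(gsets))
  for (s in seq_along(gsets)) {
    pa <- procrustes_align(gsets[[s]]$components[, seq_len(k), drop = FALSE],
                           ref)
    aligned[[s]] <- pa$aligned
    rotations[[s]] <- pa$rotation
  }
  spectra <- vapply(gsets, function(g) g$eigenvalues_all,
                    numeric(length(gsets[[1L]]$eigenvalues_all)))
  list(subject_gradients = aligned,
       group = Reduce(`+`, aligned) / length(aligned),
       report = alignment_report(rotations),
       eigenvalues_all = rowMeans(spectra),
       gradient_sets = gsets)
}

#' Merge hemispheres by Procrustes alignment
#'
#' Gradients are computed separately per hemisphere (interhemispheric
#' connections excluded); the right set is aligned to the left.
#' Eccentricity is invariant under the alignment.
#'
#' @param left,right `gradient_set`s or component matrices.
#' @return list with `left`, `right_aligned`, `rotation`, `report`.
#' @export
hemisphere_merge <- function(left, right) {
  L <- if (inherits(left, "gradient_set")) left$components else as.matrix(left)
  pa <- procrustes_align(right, L)
  list(left = L, right_aligned = pa$aligned, rotation = pa$rotation,
       report = alignment_report(list(pa$rotation)))
}

#' Run the full synthetic-study pipeline
#'
#' Executes the requested stages in dependency order on a simulated
#' discovery cohort (plus a replication cohort for transfer evaluation) and
#' returns all stage outputs. When `out_dir` is given, key tables are
#' written as delimited text together with a JSON manifest recording every
#' parameter, so identical configs reproduce identical outputs.
#'
#' @param config parameter list from [default_config()].
#' @param stages subset of
#'   `c("simulate","connectome","gradients","stats","mpc","predict")`;
#'   stages required by later ones are added automatically.
#' @param out_dir optional output directory.
#' @return named list of stage results (class `conngrad_run`).
#' @export
run_pipeline <- function(config = default_config(), stages = c(
  "simulate", "connectome", "gradients", "stats", "mpc", "predict"),
  out_dir = NULL) {
  all_stages <- c("simulate", "connectome", "gradients", "stats", "mpc",
                  "predict")
  requested <- match.arg(stages, all_stages, several.ok = TRUE)
  # core stages run as a dependency prefix; stats/mpc/predict only on request
  core_need <- max(match(requested, all_stages), 3L * ("stats" %in% requested),
                   2L * ("predict" %in% requested))
  stages <- union(all_stages[seq_len(min(core_need, 3L))],
                  intersect(requested, c("stats", "mpc", "predict")))
  res <- list(config = config)

  # --- simulate -----------------------------------------------------------
  pop <- make_population(
    subdivisions = config$mesh_subdivisions,
    roi_fraction = config$roi_fraction, k = config$n_axes,
    smoothness = config$smoothness, n_networks = config$n_networks,
    n_parcels = config$n_parcels, n_depths = config$n_depths,
    n_targets = config$n_targets, seed = config$seed)
  discovery <- make_bundle(pop, subjects = config$subjects,
                           conn_noise_sd = config$conn_noise_sd,
                           fc_noise_sd = config$fc_noise_sd,
                           fc_slope = config$fc_slope,
                           seed = config$seed)
  replication <- make_bundle(pop, subjects = config$subjects,
                             conn_noise_sd = config$conn_noise_sd,
                             fc_noise_sd = config$fc_noise_sd,
                             fc_slope = config$fc_slope,
                             seed = config$seed + 1000)
  res$population <- pop
  res$discovery <- discovery
  res$replication <- replication
  if (!"connectome" %in% stages) return(finish_run(res, out_dir))

  # --- connectome summaries ----------------------------------------------
  asg <- assign_endpoints(discovery$endpoints$endpoints, pop$mesh,
                          max_dist_mm = config$max_dist_mm)
  roi <- which(pop$mesh$roi_mask)
  geo <- geodesic_distances(pop$mesh, roi, seq_len(nrow(pop$mesh$vertices)))
  mean_conn <- Reduce(`+`, lapply(discovery$connectomes, `[[`, "weights")) /
    config$subjects
  res$connectome <- list(
    assignment = asg,
    degree = degree_centrality(discovery$connectome),
    conn_distance = connectivity_distance(
      discovery$connectome, geo, percentile = config$conn_dist_percentile),
    mean_subject_connectome = mean_conn)
  if (!"gradients" %in% stages) return(finish_run(res, out_dir))

  # --- gradients ----------------------------------------------------------
  gg <- group_gradients(discovery$connectomes, mesh = pop$mesh,
                        k = config$n_axes, config = config)
  gg_rep <- group_gradients(replication$connectomes, mesh = pop$mesh,
                            k = config$n_axes, config = config)
  # replication cohort aligned into the discovery frame
  rep_to_disc <- procrustes_align(gg_rep$group, gg$group)
  ve <- variance_explained(gg$eigenvalues_all)
  res$gradients <- list(
    discovery = gg, replication = gg_rep,
    replication_aligned = rep_to_disc$aligned,
    variance_explained_first_k = sum(ve[seq_len(config$n_axes)]),
    eccentricity = eccentricity(gg$group),
    eccentricity_replication = eccentricity(gg_rep$group),
    reproducibility_r = vapply(seq_len(config$n_axes), function(j) {
      abs(stats::cor(gg$group[, j], rep_to_disc$aligned[, j]))
    }, numeric(1L)))
  if (!"stats" %in% stages && !"mpc" %in% stages && !"predict" %in% stages) {
    return(finish_run(res, out_dir))
  }

  # --- spatially-corrected association tests ------------------------------
  if ("stats" %in% stages) {
    ecc <- res$gradients$eccentricity
    predictors <- c(list(conn_distance = res$connectome$conn_distance,
                         degree = res$connectome$degree),
                    pop$maps)
    tests <- lapply(seq_along(predictors), function(i) {
      spatial_association_test(ecc, predictors[[i]], pop$basis,
                               n_surr = config$n_surrogates,
                               seed = config$seed + i)
    })
    names(tests) <- names(predictors)
    pvals <- vapply(tests, `[[`, numeric(1L), "p_moran")
    fdr <- bh_fdr(pvals, q = config$fdr_q)
    res$stats <- list(tests = tests,
                      table = data.frame(
                        predictor = names(tests),
                        r_obs = vapply(tests, `[[`, numeric(1L), "r_obs"),
                        F_obs = vapply(tests, `[[`, numeric(1L), "F_obs"),
                        p_moran = pvals, p_fdr = fdr$adjusted,
                        rejected = fdr$rejected, row.names = NULL))
  }

  # --- MPC ----------------------------------------------------------------
  if ("mpc" %in% stages) {
    prof <- correct_axis_trend(pop$profiles)
    mpc <- mpc_matrix(prof)
    mg <- mpc_gradient(mpc, k = config$n_axes,
                       sparsity = config$mpc_sparsity)
    res$mpc <- list(
      mpc = mpc, gradients = mg,
      planted_axis_r = stats::cor(mg$components[, 1L],
                                  pop$profiles$planted_axis))
  }

  # --- prediction ---------------------------------------------------------
  if ("predict" %in% stages) {
    res$predict <- run_prediction_stage(res, config)
  }
  finish_run(res, out_dir)
}

# 5-fold network classification + FC tree regression, plus cross-cohort
# transfer (train on discovery, test on replication).
run_prediction_stage <- function(res, config) {
  pop <- res$population
  disc <- res$discovery
  repl <- res$replication
  labels <- pop$labels
  nroi <- sum(pop$mesh$roi_mask)
  pairs <- vertex_pairs(nroi)
  plan <- kfold_split(seq_len(config$subjects), k = config$k_folds,
                      seed = config$seed)
  fold_kappa <- numeric(config$k_folds)
  fold_fc_r <- vector("list", config$k_folds)
  per_vertex_r <- matrix(NA_real_, nroi, config$k_folds)
  for (f in seq_len(config$k_folds)) {
    test_ids <- plan$folds[[f]]
    train_ids <- setdiff(seq_len(config$subjects), test_ids)
    gtrain <- group_gradients(disc$connectomes[train_ids], mesh = pop$mesh,
                              k = config$n_axes, config = config)$group
    gtest <- group_gradients(disc$connectomes[test_ids], mesh = pop$mesh,
                             k = config$n_axes, config = config)$group
    gtest <- procrustes_align(gtest, gtrain)$aligned
    model <- fit_network_classifier(gtrain, labels)
    pred <- predict_networks(model, gtest)
    fold_kappa[f] <- cohens_kappa(pred$labels, labels)

    feat_train <- gradient_distance_features(gtrain, pairs)
    fc_train <- Reduce(`+`, disc$fc[train_ids]) / length(train_ids)
    tree <- fit_fc_tree(feat_train, fc_train[pairs],
                        min_leaf = config$min_leaf,
                        max_splits = config$max_splits)
    feat_test <- gradient_distance_features(gtest, pairs)
    pred_fc <- predict_fc_tree(tree, feat_test)
    emp <- vapply(disc$fc[test_ids], function(m) m[pairs],
                  numeric(nrow(pairs)))
    ev <- evaluate_fc_prediction(pred_fc, emp, pairs, n_vertices = nroi)
    fold_fc_r[[f]] <- ev$per_subject_r
    per_vertex_r[, f] <- ev$per_vertex_r
  }

  # transfer: full discovery -> replication
  gdisc <- group_gradients(disc$connectomes, mesh = pop$mesh,
                           k = config$n_axes, config = config)$group
  grepl <- group_gradients(repl$connectomes, mesh = pop$mesh,
                           k = config$n_axes, config = config)$group
  grepl <- procrustes_align(grepl, gdisc)$aligned
  model_full <- fit_network_classifier(gdisc, labels)
  transfer_kappa <- cohens_kappa(predict_networks(model_full, grepl)$labels,
                                 labels)
  tree_full <- fit_fc_tree(gradient_distance_features(gdisc, pairs),
                           (Reduce(`+`, disc$fc) / length(disc$fc))[pairs],
                           min_leaf = config$min_leaf,
                           max_splits = config$max_splits)
  pred_repl <- predict_fc_tree(tree_full,
                               gradient_distance_features(grepl, pairs))
  emp_repl <- vapply(repl$fc, function(m) m[pairs], numeric(nrow(pairs)))
  ev_repl <- evaluate_fc_prediction(pred_repl, emp_repl, pairs,
                                    n_vertices = nroi)
  list(fold_kappa = fold_kappa,
       kappa_mean = mean(fold_kappa), kappa_sd = stats::sd(fold_kappa),
       fc_per_subject_r = unlist(fold_fc_r),
       fc_r_mean = mean(unlist(fold_fc_r)),
       fc_r_sd = stats::sd(unlist(fold_fc_r)),
       fc_per_vertex_r = rowMeans(per_vertex_r),
       transfer_kappa = transfer_kappa,
       transfer_fc_r_mean = mean(ev_repl$per_subject_r),
       network_model = model_full, tree_model = tree_full)
}

finish_run <- function(res, out_dir) {
  class(res) <- "conngrad_run"
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_gifti_surface(res$population$mesh,
                      file.path(out_dir, "mesh.surf.gii"))
  if (!is.null(res$gradients)) {
    write_matrix_tsv(res$gradients$discovery$group,
                     file.path(out_dir, "gradients_group.tsv"))
    utils::write.table(
      data.frame(eccentricity = res$gradients$eccentricity),
      file.path(out_dir, "eccentricity.tsv"), sep = "\t", row.names = FALSE)
  }
  if (!is.null(res$stats)) {
    utils::write.table(res$stats$table,
                       file.path(out_dir, "association_tests.tsv"),
                       sep = "\t", row.names = FALSE)
  }
  manifest <- list(package = "conngrad",
                   version = as.character(utils::packageVersion("conngrad")),
                   config = res$config,
                   stages = intersect(c("simulate", "connectome", "gradients",
                                        "stats", "mpc", "predict"),
                                      names(res)),
                   artifacts = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res
}

#' @export
print.conngrad_run <- function(x, ...) {
  cat("conngrad pipeline run\n")
  if (!is.null(x$gradients)) {
    cat(sprintf("  variance explained (first %d gradients): %.1f%%\n",
                x$config$n_axes,
                100 * x$gradients$variance_explained_first_k))
  }
  if (!is.null(x$stats)) {
    print(x$stats$table, digits = 3)
  }
  if (!is.null(x$predict)) {
    cat(sprintf("  network kappa: %.2f +/- %.2f (transfer %.2f)\n",
                x$predict$kappa_mean, x$predict$kappa_sd,
                x$predict$transfer_kappa))
    cat(sprintf("  FC tree per-subject r: %.2f +/- %.2f\n",
                x$predict$fc_r_mean, x$predict$fc_r_sd))
  }
  invisible(x)
}
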