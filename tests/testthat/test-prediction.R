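test_that("k-fold plans are balanced, disjoint and deterministic", {
  plan <- kfold_split(1:75, k = 5, seed = 1)
  expect_equal(lengths(plan$folds), rep(15, 5))
  expect_setequal(unlist(plan$folds), 1:75)
  expect_identical(plan, kfold_split(1:75, k = 5, seed = 1))
  plan2 <- kfold_split(1:17, k = 5, seed = 2)
  expect_equal(sort(lengths(plan2$folds), decreasing = TRUE),
               c(4, 4, 3, 3, 3))
  expect_error(kfold_split(1:10, k = 1), ">= 2")
})

test_that("network classifier separates separable clusters", {
  set.seed(1)
  g <- cbind(c(stats::rnorm(30, -3), stats::rnorm(30, 3)),
             stats::rnorm(60), stats::rnorm(60))
  lab <- factor(rep(c("a", "b"), each = 30))
  model <- suppressWarnings(fit_network_classifier(g, lab))
  pred <- predict_networks(model, g)
  expect_equal(as.character(pred$labels), as.character(lab))
  expect_equal(rowSums(pred$probabilities), rep(1, 60), tolerance = 1e-10)
  expect_true(all(pred$probabilities >= 0 & pred$probabilities <= 1))
  expect_equal(model$beta[, 1], c(0, 0, 0, 0), ignore_attr = TRUE)
  expect_error(fit_network_classifier(g, factor(rep("a", 60))), "2 networks")
  expect_error(fit_network_classifier(g, factor(c("a", rep("b", 59)))),
               "10 vertices")
})

test_that("labels independent of gradients give chance-level kappa", {
  # in-sample kappa carries a small overfitting bias that shrinks with n
  set.seed(2)
  kappas <- vapply(1:30, function(r) {
    g <- matrix(stats::rnorm(900), 300, 3)
    lab <- factor(rep(c("a", "b"), each = 150))
    model <- fit_network_classifier(g, lab)
    cohens_kappa(predict_networks(model, g)$labels, lab)
  }, numeric(1))
  expect_lt(abs(mean(kappas)), 0.1)
})

test_that("zero-coefficient models fall back to the first class", {
  model <- structure(list(beta = matrix(0, 4, 3),
                          classes = c("x", "y", "z")),
                     class = "network_model")
  pred <- predict_networks(model, matrix(stats::rnorm(30), 10, 3))
  expect_true(all(pred$labels == "x"))
  expect_equal(pred$probabilities, matrix(1 / 3, 10, 3), tolerance = 1e-12)
})

test_that("Cohen's kappa matches its closed form and the brute force", {
  expect_equal(cohens_kappa(c(1, 2, 3), c(1, 2, 3)), 1)
  # printed 2x2 confusion [[20,5],[10,15]]: po = 0.7, pe = 0.5, kappa = 0.4
  a <- rep(c("p", "p", "q", "q"), c(20, 5, 10, 15))
  b <- rep(c("p", "q", "p", "q"), c(20, 5, 10, 15))
  expect_equal(cohens_kappa(a, b), 0.4)
  expect_equal(cohens_kappa(rep("c", 5), rep("c", 5)), 1)
  expect_equal(cohens_kappa(rep("c", 5), rep("d", 5)), 0)

  set.seed(3)
  for (r in 1:200) {
    n <- sample(5:40, 1)
    x <- sample(letters[1:3], n, replace = TRUE)
    y <- sample(letters[1:3], n, replace = TRUE)
    if (all(x == x[1]) && all(y == y[1]) && x[1] != y[1]) next
    expect_equal(cohens_kappa(x, y), brute_force_kappa(x, y),
                 tolerance = 1e-12)
  }
  # independent uniform labels: mean kappa ~ 0
  ks <- vapply(1:500, function(r) {
    cohens_kappa(sample(1:3, 60, replace = TRUE),
                 sample(1:3, 60, replace = TRUE))
  }, numeric(1))
  expect_lt(abs(mean(ks)), 4 * stats::sd(ks) / sqrt(500))
})

test_that("gradient distance features match the loop oracle", {
  set.seed(4)
  g <- matrix(stats::rnorm(60), 20, 3)
  pairs <- vertex_pairs(20)
  feat <- gradient_distance_features(g, pairs)
  expect_equal(nrow(feat), 190)
  for (r in sample(190, 20)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    expect_equal(unname(feat[r, 1]), sqrt(sum((g[i, ] - g[j, ])^2)))
  }
  expect_equal(unname(gradient_distance_features(g, cbind(3, 3))[1, 1]), 0)
  expect_equal(gradient_distance_features(g, cbind(2, 9)),
               gradient_distance_features(g, cbind(9, 2)))
  fa <- gradient_distance_features(g, pairs, per_axis = TRUE)
  expect_equal(ncol(fa), 4)
  expect_equal(unname(fa[1, 2]), abs(g[pairs[1, 1], 1] - g[pairs[1, 2], 1]))
})

test_that("the regression tree recovers a step function", {
  set.seed(5)
  x <- matrix(sort(stats::runif(100)), ncol = 1)
  theta <- 0.5
  y <- ifelse(x[, 1] < theta, -1, 1)
  tree <- fit_fc_tree(x, y, min_leaf = 20, max_splits = 20)
  root <- tree$nodes[[1]]
  expect_false(root$is_leaf)
  gap <- max(diff(sort(x[, 1])))
  expect_lt(abs(root$threshold - theta), gap + 1e-9)
  expect_equal(predict_fc_tree(tree, x), y)
})

test_that("tree constraints hold and SSE is monotone in max_splits", {
  set.seed(6)
  x <- cbind(stats::runif(300), stats::runif(300))
  y <- sin(4 * x[, 1]) + 0.5 * x[, 2] + stats::rnorm(300, sd = 0.1)
  leaf_sizes <- function(tree) {
    vapply(Filter(function(nd) nd$is_leaf, tree$nodes), `[[`, numeric(1), "n")
  }
  sses <- vapply(c(1, 3, 7, 12, 20), function(ms) {
    tree <- fit_fc_tree(x, y, min_leaf = 20, max_splits = ms)
    expect_lte(tree$n_splits, ms)
    expect_true(all(leaf_sizes(tree) >= 20))
    sum((predict_fc_tree(tree, x) - y)^2)
  }, numeric(1))
  expect_true(all(diff(sses) <= 1e-9))

  # constant response: single leaf predicting the constant
  tree <- fit_fc_tree(x, rep(2.5, 300))
  expect_equal(tree$n_splits, 0)
  expect_equal(predict_fc_tree(tree, x), rep(2.5, 300))
  expect_error(fit_fc_tree(x[1:10, ], y[1:10]), "min_leaf")
})

test_that("the first split agrees with an independent CART fit", {
  skip_if_not_installed("rpart")
  set.seed(7)
  x <- matrix(stats::runif(200), ncol = 1)
  y <- 2 * (x[, 1] > 0.6) + stats::rnorm(200, sd = 0.05)
  mine <- fit_fc_tree(x, y, min_leaf = 20, max_splits = 1)
  rp <- rpart::rpart(y ~ x, data = data.frame(x = x[, 1], y = y),
                     control = rpart::rpart.control(minbucket = 20, cp = 0,
                                                    maxdepth = 1, minsplit = 40,
                                                    xval = 0))
  expect_equal(mine$nodes[[1]]$threshold, rp$splits[1, "index"],
               tolerance = 1e-8)
})

test_that("FC prediction evaluation computes subject and vertex correlations", {
  set.seed(8)
  n <- 12
  pairs <- vertex_pairs(n)
  emp <- matrix(stats::rnorm(nrow(pairs) * 4), nrow(pairs), 4)
  ev <- evaluate_fc_prediction(emp, emp, pairs)
  expect_equal(ev$per_subject_r, rep(1, 4))
  expect_equal(ev$per_vertex_r, rep(1, n))
  ev <- evaluate_fc_prediction(-emp, emp, pairs)
  expect_equal(ev$per_subject_r, rep(-1, 4))

  pred <- stats::rnorm(nrow(pairs))
  ev <- evaluate_fc_prediction(pred, emp, pairs)
  expect_equal(ev$per_subject_r[2], stats::cor(pred, emp[, 2]))
  rows <- which(pairs[, 1] == 5 | pairs[, 2] == 5)
  expect_equal(ev$per_vertex_r[5],
               stats::cor(rep(pred[rows], 4), as.vector(emp[rows, ])))
})

test_that("gradients predict networks and FC on a small synthetic cohort", {
  pop <- make_population(seed = 21)
  bundle <- make_bundle(pop, subjects = 10, seed = 21)
  cfg <- default_config(seed = 21)
  gg <- group_gradients(bundle$connectomes, mesh = pop$mesh, k = 3,
                        config = cfg)
  model <- suppressWarnings(fit_network_classifier(gg$group, pop$labels))
  kap <- cohens_kappa(predict_networks(model, gg$group)$labels, pop$labels)
  expect_gt(kap, 0.8)

  nroi <- sum(pop$mesh$roi_mask)
  pairs <- vertex_pairs(nroi)
  feat <- gradient_distance_features(gg$group, pairs)
  fc_mean <- Reduce(`+`, bundle$fc) / length(bundle$fc)
  tree <- fit_fc_tree(feat, fc_mean[pairs])
  r <- stats::cor(predict_fc_tree(tree, feat), bundle$fc[[1]][pairs])
  expect_gt(r, 0.5)
})
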