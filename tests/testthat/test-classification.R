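sep_data <- function(n = 60, seed = 3) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(y * 2 + rnorm(n, sd = 0.1), matrix(rnorm(n * 3), n, 4 - 1))
  colnames(X) <- paste0("f", 1:4)
  list(X = X, y = y)
}

test_that("hyper grids respect the published ranges", {
  g <- hyper_grid("gbdt")
  expect_equal(range(g$grid$n_estimators), c(1, 40))
  expect_equal(range(g$grid$max_depth), c(1, 10))
  expect_equal(g$grid$learning_rate, c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8))
  expect_equal(range(g$grid$reg_lambda), c(1, 100))
  expect_error(hyper_grid("gbdt", grid = list(max_depth = 99)), "range")
  expect_error(hyper_grid("gbdt", grid = list(nope = 1)), "unknown")
  s <- hyper_grid("svm")
  expect_setequal(s$grid$kernel, c("linear", "poly", "rbf", "sigmoid"))
  expect_equal(range(s$grid$C), c(5, 50))
  k <- hyper_grid("knn")
  expect_equal(range(k$grid$n_neighbors), c(1, 20))
  expect_setequal(k$grid$weights, c("uniform", "distance"))
})

test_that("a singleton grid is selected as-is, and duplicates collapse", {
  d <- sep_data()
  point <- list(n_estimators = 5, max_depth = 2, learning_rate = 0.1,
                min_child_weight = 1, subsample = 1.0,
                colsample_bytree = 1.0, reg_alpha = 0, reg_lambda = 1)
  g1 <- hyper_grid("gbdt", grid = point, budget = "exhaustive")
  fit1 <- grid_search_fit(d$X, d$y, g1, seed = 1L)
  expect_equal(fit1$best_params[names(point)], point,
               ignore_attr = TRUE)
  # duplicating a value list does not change the candidate set
  g2 <- hyper_grid("gbdt", grid = c(point), budget = "exhaustive")
  fit2 <- grid_search_fit(d$X, d$y, g2, seed = 1L)
  expect_equal(fit2$best_params, fit1$best_params)
  expect_equal(fit1$n_candidates, 1L)
})

test_that("grid search never selects a point outside the declared grid", {
  d <- sep_data()
  g <- hyper_grid("gbdt", n = 25L)
  fit <- grid_search_fit(d$X, d$y, g, seed = 12L)
  for (nm in names(fit$best_params))
    expect_true(fit$best_params[[nm]] %in% g$grid[[nm]])
})

test_that("separable data is fit to a perfect training AUROC", {
  d <- sep_data()
  fit <- grid_search_fit(d$X, d$y, hyper_grid("gbdt", n = 10L), seed = 2L)
  expect_equal(auroc(d$y, predict_scores(fit, d$X)), 1.0)
})

test_that("grid search demands both classes and a non-empty grid", {
  d <- sep_data()
  expect_error(grid_search_fit(d$X, rep(0L, nrow(d$X)),
                               hyper_grid("gbdt", n = 5L)), "both classes")
})

test_that("score contracts: length, permutation equivariance, ties", {
  d <- sep_data()
  fit <- grid_search_fit(d$X, d$y, hyper_grid("gbdt", n = 5L), seed = 3L)
  s <- predict_scores(fit, d$X)
  expect_length(s, nrow(d$X))
  expect_true(all(s >= 0 & s <= 1))
  perm <- sample(nrow(d$X))
  expect_equal(predict_scores(fit, d$X[perm, ]), s[perm])
  same <- d$X[rep(1, 5), ]
  expect_equal(length(unique(predict_scores(fit, same))), 1L)
  expect_error(predict_scores(fit, d$X[, 1:2]), "mismatch")
})

test_that("SVM and KNN comparators fit and score within their grids", {
  d <- sep_data(n = 40)
  svm_fit <- grid_search_fit(d$X, d$y,
                             hyper_grid("svm", grid = list(
                               kernel = c("linear", "rbf"), C = c(5, 10),
                               degree = 3)),
                             seed = 4L)
  expect_gt(auroc(d$y, predict_scores(svm_fit, d$X)), 0.9)
  knn_fit <- grid_search_fit(d$X, d$y,
                             hyper_grid("knn", grid = list(
                               n_neighbors = c(3, 5),
                               weights = c("uniform", "distance"),
                               algorithm = "brute", leaf_size = 10,
                               p = c(1, 2))),
                             seed = 5L)
  sk <- predict_scores(knn_fit, d$X)
  expect_true(all(sk >= 0 & sk <= 1))
  expect_gt(auroc(d$y, sk), 0.9)
})

test_that("distance-weighted KNN puts all weight on exact matches", {
  X <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  colnames(X) <- c("a", "b")
  model <- tumorvae:::fit_one("knn",
                              list(n_neighbors = 3, weights = "distance",
                                   p = 2),
                              X, c(0L, 1L, 1L), seed = 1L)
  expect_equal(tumorvae:::score_one(model, X[2, , drop = FALSE]), 1)
})

test_that("cover importance aggregates additively and finds planted signal", {
  set.seed(23)
  n <- 120
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 8), n, 8)
  X[, 3] <- X[, 3] + 2.5 * y   # planted signal feature
  colnames(X) <- paste0("f", 1:8)
  g <- hyper_grid("gbdt", n = 5L)
  fits <- lapply(1:3, function(r) grid_search_fit(X, y, g, seed = 100 + r))
  rep_all <- importance_aggregate(fits)
  expect_true(all(rep_all$importance >= 0))
  expect_equal(rep_all$importance, sort(rep_all$importance,
                                        decreasing = TRUE))
  expect_true("f3" %in% utils::head(rep_all$feature, 5))
  # additivity: subset reports sum to the union report
  r12 <- importance_aggregate(fits[1:2])
  r3 <- importance_aggregate(fits[3])
  merged <- merge(r12, r3, by = "feature", all = TRUE)
  merged[is.na(merged)] <- 0
  total <- merged$importance.x + merged$importance.y
  names(total) <- merged$feature
  expect_equal(total[rep_all$feature], setNames(rep_all$importance,
                                                rep_all$feature),
               tolerance = 1e-10)
  # a single model using one feature holds all of the total
  one <- grid_search_fit(cbind(only = X[, 3], zero = 0 * X[, 1]), y,
                         hyper_grid("gbdt", grid = list(
                           n_estimators = 3, max_depth = 2,
                           learning_rate = 0.4, min_child_weight = 1,
                           subsample = 1.0, colsample_bytree = 1.0,
                           reg_alpha = 0, reg_lambda = 1),
                           budget = "exhaustive"),
                         seed = 9L)
  imp1 <- importance_aggregate(one)
  expect_equal(imp1$importance[imp1$feature == "only"] /
                 sum(imp1$importance), 1)
  # non-tree models are refused
  d <- sep_data(40)
  sv <- grid_search_fit(d$X, d$y, hyper_grid("svm", grid = list(
    kernel = "linear", C = 5, degree = 1)), seed = 1L)
  expect_error(importance_aggregate(sv), "tree")
})

test_that("label permutation drives mean test AUROC to chance", {
  set.seed(31)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5); colnames(X) <- paste0("f", 1:5)
  y <- sample(rep(c(0L, 1L), each = n / 2))
  res <- replicated_cv(list(x = X), y,
                       cv_scheme(folds = 5L, replications = 10L,
                                 seed_base = 77L),
                       hyper_grid("gbdt", n = 3L))
  expect_gt(mean(res$auroc), 0.4)
  expect_lt(mean(res$auroc), 0.6)
})
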