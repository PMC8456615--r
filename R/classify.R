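# Supervised response classifiers over any feature set: gradient-boosted
# trees (primary), kernel SVM and k-nearest neighbors (comparators), each
# tuned by seeded grid search with stratified inner cross-validation
# maximizing AUROC, plus cover-importance aggregation for tree ensembles.

#' Hyperparameter grid for a response classifier
#'
#' Returns the published search grid for one of the three classifier
#' families, optionally restricted, together with a search budget. The
#' full gradient-boosted-tree grid has roughly 7.7e8 points, so the
#' default budget is `"random_n"`: `n` seeded draws from the grid;
#' `"exhaustive"` enumerates the product and is intended for reduced
#' grids.
#'
#' @param classifier_kind `"gbdt"`, `"svm"` or `"knn"`.
#' @param grid named list of value vectors overriding the defaults; each
#'   supplied value must lie within the published range for that
#'   hyperparameter.
#' @param budget `"random_n"` or `"exhaustive"`.
#' @param n number of random draws under the `"random_n"` budget
#'   (default 1000).
#' @return A `hyper_grid` object.
#' @export
hyper_grid <- function(classifier_kind = c("gbdt", "svm", "knn"),
                       grid = list(), budget = c("random_n", "exhaustive"),
                       n = 1000L) {
  classifier_kind <- match.arg(classifier_kind)
  budget <- match.arg(budget)
  full <- switch(classifier_kind,
    gbdt = list(n_estimators = 1:40,
                max_depth = 1:10,
                learning_rate = c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8),
                min_child_weight = 1:10,
                subsample = seq(0.1, 1.0, by = 0.1),
                colsample_bytree = seq(0.1, 1.0, by = 0.1),
                reg_alpha = 0:3,
                reg_lambda = 1:100),
    svm = list(kernel = c("linear", "poly", "rbf", "sigmoid"),
               C = 5:50,
               degree = 1:20),
    knn = list(n_neighbors = 1:20,
               weights = c("uniform", "distance"),
               algorithm = c("ball_tree", "kd_tree", "brute", "auto"),
               leaf_size = 1:20,
               p = 1:4))
  if (length(grid)) {
    bad <- setdiff(names(grid), names(full))
    if (length(bad)) stop("unknown hyperparameter(s): ",
                          paste(bad, collapse = ", "))
    for (nm in names(grid)) {
      if (!all(grid[[nm]] %in% full[[nm]]))
        stop("values for '", nm, "' outside the published range")
      full[[nm]] <- grid[[nm]]
    }
  }
  size <- prod(vapply(full, length, numeric(1)))
  structure(list(classifier_kind = classifier_kind, grid = full,
                 budget = budget, n = as.integer(n), size = size),
            class = "hyper_grid")
}

#' @export
print.hyper_grid <- function(x, ...) {
  cat(sprintf("hyper_grid [%s]: %s points, budget %s%s\n",
              x$classifier_kind, format(x$size, big.mark = ","),
              x$budget,
              if (x$budget == "random_n") sprintf(" (n = %d)", x$n) else ""))
  invisible(x)
}

# enumerate or sample candidate grid points (list of named lists),
# deduplicated with stable order so duplicated points behave as one
grid_candidates <- function(hg, seed) {
  gr <- hg$grid
  if (hg$budget == "exhaustive") {
    if (hg$size > 2e5)
      stop("exhaustive budget over ", format(hg$size, big.mark = ","),
           " points; use budget = 'random_n' or reduce the grid")
    df <- expand.grid(gr, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    n_draw <- min(hg$n, hg$size)
    df <- with_local_seed(seed, {
      as.data.frame(lapply(gr, function(v)
        v[sample.int(length(v), n_draw, replace = TRUE)]),
        stringsAsFactors = FALSE)
    })
  }
  df <- df[!duplicated(df), , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# stratified fold assignment: within each class, a seeded permutation is
# dealt round-robin into k folds
make_stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- (sample(seq_along(idx)) %% k) + 1L
    }
  })
  folds
}

# dtrain may be a prebuilt xgb.DMatrix for X/y (reused across grid
# candidates to avoid rebuilding one per fit)
fit_one <- function(kind, params, X, y, seed, dtrain = NULL) {
  if (kind == "gbdt") {
    with_local_seed(seed, {
      if (is.null(dtrain)) dtrain <- xgboost::xgb.DMatrix(X, label = y)
      booster <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$learning_rate,
                      max_depth = params$max_depth,
                      min_child_weight = params$min_child_weight,
                      subsample = params$subsample,
                      colsample_bytree = params$colsample_bytree,
                      alpha = params$reg_alpha,
                      lambda = params$reg_lambda,
                      gamma = 0,             # fixed, as published
                      nthread = 1),
        data = dtrain, nrounds = params$n_estimators, verbose = 0)
      list(kind = kind, booster = booster)
    })
  } else if (kind == "svm") {
    kmap <- c(linear = "linear", poly = "polynomial", rbf = "radial",
              sigmoid = "sigmoid")
    with_local_seed(seed, {
      fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                        kernel = kmap[[params$kernel]], cost = params$C,
                        degree = params$degree, probability = TRUE,
                        scale = FALSE)
      list(kind = kind, svm = fit)
    })
  } else {  # knn: a lazy learner, the "model" is the training set
    list(kind = kind, X = X, y = y,
         k = params$n_neighbors, weights = params$weights, p = params$p)
  }
}

score_one <- function(model, X, dtest = NULL) {
  if (model$kind == "gbdt") {
    if (is.null(dtest)) dtest <- xgboost::xgb.DMatrix(X)
    as.numeric(stats::predict(model$booster, dtest))
  } else if (model$kind == "svm") {
    pr <- tryCatch({
      p <- stats::predict(model$svm, X, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    }, error = function(e) NULL)
    if (is.null(pr)) {  # Platt fit can fail on tiny folds; fall back to
      dv <- attr(stats::predict(model$svm, X, decision.values = TRUE),
                 "decision.values")  # monotone decision values
      sgn <- if (colnames(dv)[1L] == "0") -1 else 1
      pr <- stats::plogis(sgn * as.numeric(dv))
    }
    as.numeric(pr)
  } else {
    apply(X, 1, function(q) {
      d <- (rowSums(abs(sweep(model$X, 2, q, `-`))^model$p))^(1 / model$p)
      nb <- order(d)[seq_len(min(model$k, length(d)))]
      if (model$weights == "uniform") {
        mean(model$y[nb])
      } else if (any(d[nb] == 0)) {
        mean(model$y[nb[d[nb] == 0]])   # exact matches dominate
      } else {
        w <- 1 / d[nb]
        sum(w * model$y[nb]) / sum(w)
      }
    })
  }
}

#' Tune and fit a classifier by seeded grid search
#'
#' Evaluates candidate hyperparameter points (all of them under an
#' exhaustive budget, otherwise `n` seeded draws) by stratified
#' `inner_folds`-fold cross-validation on the training data, selects the
#' point with the highest mean validation AUROC (stable first-wins
#' tie-break), and refits it on all training data.
#'
#' @param X samples x features numeric matrix.
#' @param y binary 0/1 labels (both classes must be present).
#' @param grid a [hyper_grid()]; default is the gradient-boosted-tree grid
#'   with a 1000-draw random budget.
#' @param inner_folds inner cross-validation folds (default 5).
#' @param seed integer seed controlling candidate draws, folds and fits.
#' @return A `fit_result`: `classifier_kind`, `best_params`,
#'   `inner_cv_score`, `model`, `feature_names`, `seed`.
#' @export
grid_search_fit <- function(X, y, grid = hyper_grid("gbdt"),
                            inner_folds = 5L, seed = 1L) {
  if (!inherits(grid, "hyper_grid")) stop("'grid' must be a hyper_grid")
  X <- as.matrix(X)
  y <- check_binary(y)
  if (length(unique(y)) < 2L)
    stop("grid search needs both classes present in 'y'")
  cand <- grid_candidates(grid, seed)
  if (!length(cand)) stop("empty hyperparameter grid")
  folds <- make_stratified_folds(y, inner_folds, seed + 1L)
  is_gbdt <- grid$classifier_kind == "gbdt"
  # build fold matrices (and DMatrix handles for the tree ensemble) once,
  # shared by all grid candidates
  fold_data <- lapply(seq_len(inner_folds), function(f) {
    tr <- folds != f
    fd <- list(Xtr = X[tr, , drop = FALSE], ytr = y[tr],
               Xte = X[!tr, , drop = FALSE], yte = y[!tr])
    fd$ok <- length(unique(fd$ytr)) >= 2L && length(unique(fd$yte)) >= 2L
    if (is_gbdt && fd$ok) {
      fd$dtrain <- xgboost::xgb.DMatrix(fd$Xtr, label = fd$ytr)
      fd$dtest <- xgboost::xgb.DMatrix(fd$Xte)
    }
    fd
  })
  scores <- vapply(seq_along(cand), function(ci) {
    aucs <- vapply(seq_len(inner_folds), function(f) {
      fd <- fold_data[[f]]
      if (!fd$ok) return(NA_real_)
      mod <- fit_one(grid$classifier_kind, cand[[ci]], fd$Xtr, fd$ytr,
                     seed + 100L * ci + f, dtrain = fd$dtrain)
      auroc(fd$yte, score_one(mod, fd$Xte, dtest = fd$dtest))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)  # stable: first index at the maximum
  model <- fit_one(grid$classifier_kind, cand[[best]], X, y, seed + 7L)
  structure(list(classifier_kind = grid$classifier_kind,
                 best_params = cand[[best]],
                 inner_cv_score = scores[best],
                 model = model,
                 feature_names = colnames(X),
                 n_candidates = length(cand),
                 seed = as.integer(seed)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: inner-CV AUROC %.3f over %d candidates\n",
              x$classifier_kind, x$inner_cv_score, x$n_candidates))
  cat("  best:", paste(names(x$best_params), unlist(x$best_params),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict response scores (probability of progression)
#'
#' @param fit a `fit_result` from [grid_search_fit()].
#' @param X samples x features matrix with the same feature count the
#'   model was trained on.
#' @return Numeric vector of scores in `[0, 1]`, one per row of `X`.
#' @export
predict_scores <- function(fit, X) {
  if (!inherits(fit, "fit_result")) stop("'fit' must be a fit_result")
  X <- as.matrix(X)
  if (!is.null(fit$feature_names) && ncol(X) != length(fit$feature_names))
    stop("feature count mismatch: model has ", length(fit$feature_names),
         ", data has ", ncol(X))
  score_one(fit$model, X)
}

#' Aggregate tree-ensemble cover importance across replications
#'
#' Sums per-feature cover-type importance scores over a set of fitted
#' gradient-boosted-tree models (e.g., one per cross-validation
#' replication), ranking features by the total.
#'
#' @param fits a `fit_result` or list of `fit_result`s, all `"gbdt"`.
#' @param top_n optionally truncate the report to the `top_n` features.
#' @return An `importance_report` data.frame: `feature`, `importance`
#'   (summed cover score, >= 0), sorted decreasing.
#' @export
importance_aggregate <- function(fits, top_n = NULL) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  if (!length(fits)) stop("need at least one fitted model")
  total <- numeric(0)
  for (f in fits) {
    if (!inherits(f, "fit_result") || f$classifier_kind != "gbdt")
      stop("importance aggregation requires tree-ensemble (gbdt) fits")
    imp <- xgboost::xgb.importance(model = f$model$booster)
    if (is.null(imp) || !nrow(imp)) next
    v <- imp$Cover
    names(v) <- imp$Feature
    for (nm in names(v))
      total[nm] <- if (nm %in% names(total)) total[nm] + v[[nm]] else v[[nm]]
  }
  # carry along never-used features with zero importance
  all_feats <- unique(unlist(lapply(fits, `[[`, "feature_names")))
  missing <- setdiff(all_feats, names(total))
  if (length(missing)) total[missing] <- 0
  out <- data.frame(feature = names(total), importance = unname(total),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  class(out) <- c("importance_report", class(out))
  out
}
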