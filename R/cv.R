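# Replicated cross-validation harness: R replications of k-fold CV with
# out-of-fold score pooling (one AUROC and one AUPRC per replication and
# feature set), and the comparison table contrasting feature sets via
# logit-scale Welch tests.

#' Replicated cross-validation scheme
#'
#' @param folds number of folds per replication (default 5).
#' @param replications number of replications (default 30); each
#'   replication re-assigns samples to folds with seed `seed_base + r`.
#' @param seed_base integer base seed.
#' @param stratified stratify folds by class (default `TRUE`; with the
#'   class imbalances typical of response cohorts, unstratified folds can
#'   easily contain a single class).
#' @return A `cv_scheme` object.
#' @export
cv_scheme <- function(folds = 5L, replications = 30L, seed_base = 0L,
                      stratified = TRUE) {
  if (folds < 2L) stop("'folds' must be >= 2")
  if (replications < 1L) stop("'replications' must be >= 1")
  structure(list(folds = as.integer(folds),
                 replications = as.integer(replications),
                 seed_base = as.integer(seed_base),
                 stratified = isTRUE(stratified)),
            class = "cv_scheme")
}

#' Replicated k-fold cross-validation over one or more feature sets
#'
#' For each replication, samples are assigned to folds from seed
#' `seed_base + r`; within a replication, each sample's prediction score is
#' taken from the fold in which it was in the test set, and the pooled
#' scores yield one AUROC and one AUPRC per feature set. Hyperparameter
#' tuning ([grid_search_fit()]) runs inside every training fold.
#'
#' @param X_by_featureset a samples x features matrix, or a named list of
#'   such matrices (one per feature set) over the same samples.
#' @param y binary 0/1 labels for those samples.
#' @param scheme a [cv_scheme()].
#' @param grid a [hyper_grid()] used for every feature set, or a named
#'   list of grids parallel to `X_by_featureset`.
#' @return A `replication_result`: matrices `auroc` and `auprc`
#'   (replications x feature sets), `oof_scores` (list per feature set of
#'   replications x samples out-of-fold score matrices), `fold_of`
#'   (replications x samples fold assignments), `scheme`.
#' @export
replicated_cv <- function(X_by_featureset, y, scheme = cv_scheme(),
                          grid = hyper_grid("gbdt")) {
  if (!is.list(X_by_featureset)) X_by_featureset <- list(features = X_by_featureset)
  if (is.null(names(X_by_featureset)) || any(!nzchar(names(X_by_featureset))))
    stop("'X_by_featureset' must be a named list of matrices")
  y <- check_binary(y)
  n <- length(y)
  for (nm in names(X_by_featureset)) {
    X_by_featureset[[nm]] <- as.matrix(X_by_featureset[[nm]])
    if (nrow(X_by_featureset[[nm]]) != n)
      stop("feature set '", nm, "' row count does not match labels")
  }
  if (n < scheme$folds) stop("fewer labeled samples than folds")
  grids <- if (inherits(grid, "hyper_grid"))
    stats::setNames(rep(list(grid), length(X_by_featureset)),
                    names(X_by_featureset))
  else grid
  methods <- names(X_by_featureset)
  R <- scheme$replications
  au_roc <- au_prc <- matrix(NA_real_, R, length(methods),
                             dimnames = list(NULL, methods))
  oof <- lapply(methods, function(.) matrix(NA_real_, R, n))
  names(oof) <- methods
  fold_of <- matrix(NA_integer_, R, n)
  for (r in seq_len(R)) {
    rep_seed <- scheme$seed_base + r
    folds <- if (scheme$stratified)
      make_stratified_folds(y, scheme$folds, rep_seed)
    else with_local_seed(rep_seed, (sample.int(n) %% scheme$folds) + 1L)
    for (f in seq_len(scheme$folds))
      if (length(unique(y[folds == f])) < 2L && !scheme$stratified)
        stop("fold ", f, " in replication ", r, " contains a single class; ",
             "enable stratification (cv_scheme(stratified = TRUE))")
    fold_of[r, ] <- folds
    for (mi in seq_along(methods)) {
      nm <- methods[mi]
      X <- X_by_featureset[[nm]]
      pooled <- rep(NA_real_, n)
      for (f in seq_len(scheme$folds)) {
        test <- folds == f
        fit <- grid_search_fit(X[!test, , drop = FALSE], y[!test],
                               grid = grids[[nm]],
                               seed = rep_seed * 1000L + f * 10L + mi)
        pooled[test] <- predict_scores(fit, X[test, , drop = FALSE])
      }
      oof[[nm]][r, ] <- pooled
      au_roc[r, mi] <- auroc(y, pooled)
      au_prc[r, mi] <- auprc(y, pooled)
    }
    gc(verbose = FALSE)  # release booster/DMatrix handles between reps
  }
  structure(list(auroc = au_roc, auprc = au_prc, oof_scores = oof,
                 fold_of = fold_of, y = y, scheme = scheme),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("replication_result: %d replications x %d-fold CV, %d samples\n",
              x$scheme$replications, x$scheme$folds, length(x$y)))
  cat("mean pooled AUROC per feature set:\n")
  print(round(colMeans(x$auroc), 4))
  invisible(x)
}

#' Build the feature-set comparison table
#'
#' Mean pooled AUROC/AUPRC per feature set across replications, pairwise
#' logit-scale Welch p-values of a reference feature set against each
#' other, and a best-method flag on mean AUROC (ties flagged).
#'
#' @param result a [replicated_cv()] result, or a named list of
#'   replication-value vectors (then only AUROC columns are produced).
#' @param reference name of the feature set compared against the others
#'   (default `"vae"` when present, else the first).
#' @return A `comparison_table` data.frame: one row per feature set with
#'   `mean_auroc`, `mean_auprc`, `p_auroc_vs_ref`, `p_auprc_vs_ref`,
#'   `best`, `tied`.
#' @export
build_comparison_table <- function(result, reference = NULL) {
  if (inherits(result, "replication_result")) {
    roc <- result$auroc
    prc <- result$auprc
  } else {
    lens <- vapply(result, length, numeric(1))
    if (length(unique(lens)) != 1L)
      stop("replication vectors have differing lengths")
    roc <- do.call(cbind, result)
    prc <- NULL
  }
  methods <- colnames(roc)
  if (is.null(reference))
    reference <- if ("vae" %in% methods) "vae" else methods[1L]
  if (!reference %in% methods) stop("unknown reference method: ", reference)
  p_roc <- p_prc <- rep(NA_real_, length(methods))
  for (i in seq_along(methods)) {
    if (methods[i] == reference) next
    p_roc[i] <- logit_welch_compare(roc[, reference], roc[, i])$p_value
    if (!is.null(prc))
      p_prc[i] <- logit_welch_compare(prc[, reference], prc[, i])$p_value
  }
  mean_roc <- colMeans(roc)
  best <- mean_roc == max(mean_roc)
  out <- data.frame(method = methods,
                    mean_auroc = unname(mean_roc),
                    mean_auprc = if (!is.null(prc)) unname(colMeans(prc))
                                 else NA_real_,
                    p_auroc_vs_ref = p_roc,
                    p_auprc_vs_ref = p_prc,
                    best = unname(best),
                    tied = sum(best) > 1L,
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  class(out) <- c("comparison_table", class(out))
  rownames(out) <- NULL
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("comparison_table (reference:", attr(x, "reference"), ")\n")
  df <- as.data.frame(x)
  df$mean_auroc <- round(df$mean_auroc, 4)
  df$mean_auprc <- round(df$mean_auprc, 4)
  df$p_auroc_vs_ref <- signif(df$p_auroc_vs_ref, 3)
  df$p_auprc_vs_ref <- signif(df$p_auprc_vs_ref, 3)
  print(df)
  invisible(x)
}
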