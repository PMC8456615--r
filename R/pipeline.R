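# End-to-end semi-supervised study: preprocess a cohort, fit the
# unsupervised encoders on all samples (labeled and unlabeled), encode the
# labeled subset, and compare feature sets with the replicated-CV harness.

#' Construct competing feature sets from scaled expression data
#'
#' Fits each requested encoder on *all* samples (the semi-supervised step)
#' and returns the per-sample feature matrices used downstream: `raw` (the
#' scaled expression itself), `vae` (a sampled latent encoding), `ae`
#' (deterministic autoencoder code), `pca` (components at a cumulative
#' variance threshold) and `ica` (FastICA with the PCA-matched component
#' count).
#'
#' @param features a [feature_matrix()] in state `"minmax"`.
#' @param methods subset of `c("raw", "vae", "ae", "pca", "ica")`.
#' @param latent_dim,n_layers,loss VAE/AE architecture settings.
#' @param variance_threshold cumulative-variance cutoff for PCA (and the
#'   ICA component count), default 0.9.
#' @param epochs,batch_size training settings for the neural encoders.
#' @param deterministic_encoding use `z = mu` instead of a sampled latent
#'   draw for the VAE features (default `FALSE`: one draw, as used for
#'   supervised learning downstream).
#' @param seed integer seed.
#' @return A list with `sets` (named list of samples x features matrices)
#'   and `models` (the fitted encoders).
#' @export
build_feature_sets <- function(features,
                               methods = c("raw", "vae", "ae", "pca", "ica"),
                               latent_dim = 16L, n_layers = 2L, loss = "l1",
                               variance_threshold = 0.9, epochs = 300L,
                               batch_size = 64L,
                               deterministic_encoding = FALSE, seed = 1L) {
  assert_state(features, "minmax")
  methods <- match.arg(methods, several.ok = TRUE)
  xm <- fm_values(features)
  sets <- list(); models <- list()
  if ("raw" %in% methods) sets$raw <- xm
  if ("vae" %in% methods) {
    models$vae <- vae(features, latent_dim = latent_dim,
                      n_layers = n_layers, loss = loss, epochs = epochs,
                      batch_size = batch_size, seed = seed)
    sets$vae <- encode(models$vae, xm,
                       deterministic = deterministic_encoding,
                       seed = seed + 1L)$z
  }
  if ("ae" %in% methods) {
    models$ae <- autoencoder(features, latent_dim = latent_dim,
                             n_layers = n_layers, loss = loss,
                             epochs = epochs, batch_size = batch_size,
                             seed = seed)
    sets$ae <- ae_encode(models$ae, xm)
  }
  if ("pca" %in% methods || "ica" %in% methods) {
    models$pca <- pca_fit(xm, variance_threshold = variance_threshold)
    if ("pca" %in% methods) sets$pca <- pca_transform(models$pca, xm)
    if ("ica" %in% methods) {
      models$ica <- ica_fit(xm, n_components = models$pca$k, seed = seed)
      sets$ica <- ica_transform(models$ica, xm)
    }
  }
  list(sets = sets[intersect(methods, names(sets))], models = models)
}

#' Run the full semi-supervised response-prediction study on a cohort
#'
#' The three-step recipe, measured by replicated cross-validation:
#' (1) preprocess (variance filter, log-normalize, min-max scale) and fit
#' the unsupervised encoders on all samples; (2) encode the clinically
#' labeled subset; (3) tune and evaluate a supervised classifier per
#' feature set with replicated stratified k-fold CV, pooling out-of-fold
#' scores into one AUROC/AUPRC per replication, and contrast feature sets
#' with logit-scale Welch tests.
#'
#' @param cohort a [generate_cohort()] result, or a list with elements
#'   `counts`, `abundance` ([feature_matrix()]s), `label_of` (named 0/1/NA)
#'   and optionally `type_of` (used as the variance-filter grouping).
#' @param methods feature sets to compare (see [build_feature_sets()]).
#' @param scheme a [cv_scheme()].
#' @param grid a [hyper_grid()] (default: gradient-boosted trees with a
#'   random 50-draw budget per tuning call).
#' @param quantile top-variance gene quantile (default 0.20).
#' @param ... further arguments passed to [build_feature_sets()].
#' @param seed integer seed.
#' @return A list: `result` ([replicated_cv()] output), `table`
#'   ([build_comparison_table()] output), `features`, `models`, `labeled`
#'   (ids of labeled samples).
#' @export
run_response_study <- function(cohort,
                               methods = c("raw", "vae", "pca", "ica"),
                               scheme = cv_scheme(replications = 5L),
                               grid = hyper_grid("gbdt", n = 50L),
                               quantile = 0.20, ..., seed = 1L) {
  prep <- preprocess_cohort(cohort$counts, cohort$abundance,
                            group = cohort$type_of, quantile = quantile)
  fs <- build_feature_sets(prep$features, methods = methods, seed = seed,
                           ...)
  labeled <- which(!is.na(cohort$label_of))
  y <- cohort$label_of[labeled]
  sets_labeled <- lapply(fs$sets, function(m) m[labeled, , drop = FALSE])
  res <- replicated_cv(sets_labeled, y, scheme = scheme, grid = grid)
  list(result = res, table = build_comparison_table(res),
       features = prep$features, models = fs$models,
       labeled = names(cohort$label_of)[labeled])
}
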