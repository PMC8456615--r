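# Feature construction: log2 total-count normalization, MAD-based
# high-variance gene filtering with per-group union, and min-max scaling
# onto [0,1] (the encoder's input contract).

#' Total-count normalize and log2-transform a count matrix
#'
#' Each sample's counts are divided by the sample total, rescaled to a
#' common target depth, and transformed as `log2(1 + C)`. Doubling every
#' count in a sample therefore leaves that sample's output unchanged.
#'
#' @param counts a [feature_matrix()] in state `"counts"`.
#' @param target_depth common library depth to rescale to; default is the
#'   cohort's median library size.
#' @return A [feature_matrix()] in state `"log_norm"`, same dimensions and
#'   order.
#' @export
log_total_count_normalize <- function(counts, target_depth = NULL) {
  assert_state(counts, "counts")
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  if (is.null(target_depth)) target_depth <- stats::median(totals)
  if (!is.finite(target_depth) || target_depth <= 0)
    stop("'target_depth' must be a positive number")
  scaled <- sweep(fm_values(counts), 1, totals / target_depth, `/`)
  feature_matrix(log2(1 + scaled), "log_norm")
}

#' Per-gene median absolute deviation across samples
#'
#' Robust per-gene variability, computed as `stats::mad()` with its default
#' normal-consistency constant 1.4826. Scores are rank-equivalent to the
#' unscaled MAD, so gene selection is unaffected by the constant.
#'
#' @param abundance a [feature_matrix()] (any state; typically FPKM-like
#'   abundances, which mitigate gene-length and depth bias).
#' @return Named numeric vector of nonnegative per-gene MAD scores.
#' @export
mad_per_gene <- function(abundance) {
  if (!is_feature_matrix(abundance)) stop("'abundance' must be a feature_matrix")
  if (nrow(abundance) < 2L)
    stop("MAD across samples needs at least 2 samples")
  apply(fm_values(abundance), 2, stats::mad)
}

#' Select top-variance genes per group and take the union
#'
#' Within each group (e.g., cancer type), the `ceiling(quantile * n_genes)`
#' genes with the highest MAD are selected; genes tied with the cutoff score
#' are kept (inclusive tie rule), and the union across groups is returned in
#' lexicographic gene-id order for a reproducible feature order.
#'
#' @param abundance_by_group named list of [feature_matrix()] objects, one
#'   per group, sharing the same gene universe.
#' @param quantile proportion of top-variable genes to keep per group
#'   (default 0.20).
#' @return A `gene_filter_result` list: `selected_ids` (union, sorted),
#'   `per_group` (list of per-group selections), `mad_scores` (group x gene
#'   matrix), `quantile`.
#' @export
select_top_variance_union <- function(abundance_by_group, quantile = 0.20) {
  if (!length(abundance_by_group)) stop("no groups given")
  if (!is.list(abundance_by_group)) abundance_by_group <- list(abundance_by_group)
  if (quantile <= 0 || quantile > 1) stop("'quantile' must be in (0, 1]")
  genes <- colnames(abundance_by_group[[1L]])
  for (g in abundance_by_group) {
    if (!is_feature_matrix(g)) stop("each group must be a feature_matrix")
    if (!identical(colnames(g), genes))
      stop("all groups must share the same gene universe (and order)")
    if (nrow(g) < 2L) stop("each group needs at least 2 samples")
  }
  n_keep <- ceiling(quantile * length(genes))
  scores <- t(vapply(abundance_by_group, mad_per_gene, numeric(length(genes))))
  per_group <- lapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    cutoff <- sort(s, decreasing = TRUE)[n_keep]
    genes[s >= cutoff]  # inclusive at ties with the boundary score
  })
  names(per_group) <- names(abundance_by_group)
  structure(list(selected_ids = sort(unique(unlist(per_group))),
                 per_group = per_group,
                 mad_scores = scores,
                 quantile = quantile),
            class = "gene_filter_result")
}

#' @export
print.gene_filter_result <- function(x, ...) {
  cat(sprintf("gene_filter_result: top %.0f%% by MAD in %d group(s) -> %d genes\n",
              100 * x$quantile, length(x$per_group), length(x$selected_ids)))
  invisible(x)
}

#' Min-max scaling fitted on a reference cohort
#'
#' `minmax_fit()` records per-feature minima and maxima on the reference
#' set (in the semi-supervised pipeline: all samples, labeled and
#' unlabeled). `minmax_apply()` rescales any matrix over the same features
#' to `[0, 1]`, clipping values outside the reference range; features that
#' were constant in the reference map to 0.
#'
#' @param reference a [feature_matrix()] in state `"log_norm"`.
#' @return `minmax_fit()`: a `minmax_params` object. `minmax_apply()`: a
#'   [feature_matrix()] in state `"minmax"`.
#' @export
minmax_fit <- function(reference) {
  assert_state(reference, "log_norm")
  v <- fm_values(reference)
  structure(list(min = apply(v, 2, min), max = apply(v, 2, max),
                 feature_ids = colnames(v)),
            class = "minmax_params")
}

#' @rdname minmax_fit
#' @param x a [feature_matrix()] in state `"log_norm"` over the fitted
#'   features.
#' @param params a `minmax_params` object from `minmax_fit()`.
#' @export
minmax_apply <- function(x, params) {
  if (!inherits(params, "minmax_params"))
    stop("'params' must come from minmax_fit(); got unfitted or foreign object")
  assert_state(x, "log_norm")
  if (!identical(colnames(x), params$feature_ids))
    stop("feature ids of 'x' do not match the fitted min-max params")
  rng <- params$max - params$min
  out <- sweep(fm_values(x), 2, params$min, `-`)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), `/`)
  out[, rng == 0] <- 0  # constant reference features carry no signal
  out <- pmin(pmax(out, 0), 1)
  feature_matrix(out, "minmax")
}

#' Full preprocessing pipeline: filter, normalize, scale
#'
#' Convenience wrapper reproducing the feature-construction path: MAD
#' variance filtering on abundances (per cancer type, union of top-quantile
#' sets), `log2(1+C)` total-count normalization of the counts restricted to
#' the selected genes, and min-max scaling fitted on all samples.
#'
#' @param counts,abundance [feature_matrix()] objects (samples x genes).
#' @param group optional per-sample grouping (cancer type) for the variance
#'   filter; default one group.
#' @param quantile top-variance quantile, default 0.20.
#' @return A list: `features` (state `"minmax"`, the encoder input),
#'   `filter` (the [select_top_variance_union()] result), `minmax`
#'   (fitted params), `log_norm` (intermediate matrix).
#' @export
preprocess_cohort <- function(counts, abundance, group = NULL, quantile = 0.20) {
  assert_state(counts, "counts")
  if (is.null(group)) group <- rep("all", nrow(abundance))
  by_group <- lapply(split(seq_len(nrow(abundance)), group), function(idx)
    feature_matrix(fm_values(abundance)[idx, , drop = FALSE],
                   fm_state(abundance)))
  filt <- select_top_variance_union(by_group, quantile = quantile)
  ln <- log_total_count_normalize(counts)
  ln <- feature_matrix(fm_values(ln)[, filt$selected_ids, drop = FALSE],
                       "log_norm")
  mm <- minmax_fit(ln)
  list(features = minmax_apply(ln, mm), filter = filt, minmax = mm,
       log_norm = ln)
}
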