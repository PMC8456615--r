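# Linear baseline encoders: PCA at a cumulative-variance threshold (exact
# SVD via prcomp) and FastICA with a matched component count. FastICA
# (logcosh contrast, symmetric decorrelation) is implemented here because
# the output is canonicalized -- component signs fixed by the
# largest-magnitude loading, components ordered by signal power -- so that
# feature indices in downstream importance reports are reproducible.

#' Fit PCA keeping enough components for a variance threshold
#'
#' Exact-SVD principal components; `k` is the smallest component count
#' whose cumulative explained variance reaches `variance_threshold`.
#'
#' @param data samples x features matrix (or [feature_matrix()]).
#' @param variance_threshold proportion of variance to retain, in (0, 1];
#'   default 0.9.
#' @return A `linear_embedding` (kind `"pca"`): `components` (features x
#'   k loadings), `center`, `explained_variance_ratio`, `k`.
#' @export
pca_fit <- function(data, variance_threshold = 0.9) {
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("'variance_threshold' must be in (0, 1]")
  xm <- if (is_feature_matrix(data)) fm_values(data) else as.matrix(data)
  if (nrow(xm) < 2L) stop("PCA needs at least 2 samples")
  pc <- stats::prcomp(xm, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(evr) >= variance_threshold - 1e-12)[1L]
  structure(list(kind = "pca",
                 components = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center,
                 explained_variance_ratio = evr[seq_len(k)],
                 k = k),
            class = "linear_embedding")
}

#' Project samples onto a fitted linear embedding
#'
#' @param embedding a `linear_embedding` from [pca_fit()] or [ica_fit()].
#' @param x samples x features matrix over the fitted feature set.
#' @return Samples x k matrix of component scores.
#' @export
linear_transform <- function(embedding, x) {
  if (!inherits(embedding, "linear_embedding"))
    stop("'embedding' must come from pca_fit() or ica_fit()")
  xm <- if (is_feature_matrix(x)) fm_values(x) else as.matrix(x)
  if (is.null(dim(xm))) xm <- matrix(xm, 1)
  if (ncol(xm) != length(embedding$center))
    stop("feature count mismatch with fitted embedding")
  sweep(xm, 2, embedding$center, `-`) %*% embedding$components
}

#' @rdname linear_transform
#' @export
pca_transform <- function(embedding, x) {
  if (embedding$kind != "pca") stop("'embedding' is not a PCA fit")
  linear_transform(embedding, x)
}

#' @rdname linear_transform
#' @export
ica_transform <- function(embedding, x) {
  if (embedding$kind != "ica") stop("'embedding' is not an ICA fit")
  linear_transform(embedding, x)
}

#' Fit FastICA with a fixed component count
#'
#' Centers and PCA-whitens the data, then runs the symmetric fixed-point
#' FastICA iteration with the logcosh contrast. Components are
#' canonicalized for reproducibility: each component's largest-magnitude
#' loading is made positive, and components are ordered by decreasing
#' signal power (variance of the projected training data before unit
#' scaling). Non-convergence within `max_iter` is not an error: a warning
#' is raised and the result carries `converged = FALSE`.
#'
#' @param data samples x features matrix (or [feature_matrix()]).
#' @param n_components number of independent components (typically the
#'   matched PCA component count).
#' @param max_iter,tol fixed-point iteration controls.
#' @param seed RNG seed for the random orthogonal initialization.
#' @return A `linear_embedding` (kind `"ica"`): `components` (features x
#'   k, i.e. the unmixing applied after centering), `center`, `k`,
#'   `converged`.
#' @export
ica_fit <- function(data, n_components, max_iter = 200L, tol = 1e-6,
                    seed = 1L) {
  xm <- if (is_feature_matrix(data)) fm_values(data) else as.matrix(data)
  n <- nrow(xm)
  k <- as.integer(n_components)
  if (k < 1L || k > min(dim(xm)))
    stop("'n_components' must be in [1, min(samples, features)]")
  center <- colMeans(xm)
  xc <- sweep(xm, 2, center, `-`)
  # PCA whitening to k dimensions
  sv <- svd(xc, nu = 0, nv = k)
  d <- sv$d[seq_len(k)]
  if (any(d < 1e-12)) stop("data rank is below 'n_components'")
  K <- sv$v %*% diag(sqrt(n - 1) / d, k)     # features x k whitening
  Z <- xc %*% K                              # whitened, unit covariance
  W <- with_local_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)                 # n x k source estimates
    G <- tanh(WX)                    # logcosh contrast derivative
    gprime <- 1 - G^2
    W_new <- crossprod(G, Z) / n - diag(colMeans(gprime), k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("FastICA did not converge in ", max_iter,
            " iterations; returning the last iterate")
  unmix <- K %*% t(W)                # features x k: xc %*% unmix = sources
  # canonicalize: order by projected signal power, fix sign by the
  # largest-magnitude loading
  S <- xc %*% unmix
  ord <- order(apply(S, 2, stats::var), decreasing = TRUE)
  unmix <- unmix[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(unmix[, j]))
    if (unmix[i_max, j] < 0) unmix[, j] <- -unmix[, j]
  }
  colnames(unmix) <- paste0("IC", seq_len(k))
  structure(list(kind = "ica", components = unmix, center = center,
                 k = k, converged = converged),
            class = "linear_embedding")
}

#' @export
print.linear_embedding <- function(x, ...) {
  cat(sprintf("linear_embedding [%s]: %d features -> %d components\n",
              x$kind, nrow(x$components), x$k))
  if (x$kind == "pca")
    cat(sprintf("  cumulative explained variance: %.3f\n",
                sum(x$explained_variance_ratio)))
  if (x$kind == "ica" && !x$converged)
    cat("  (fixed-point iteration did not converge)\n")
  invisible(x)
}
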