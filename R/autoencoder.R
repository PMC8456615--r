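#' Fit a plain (non-variational) autoencoder
#'
#' The comparison encoder: identical network shapes to the matched VAE but
#' with a deterministic bottleneck (`z = mu` head, no sampling) and trained
#' on reconstruction loss only (KL weight 0). Implemented through the same
#' machinery as [vae()], so the two models differ exactly by the KL and
#' sampling terms; the unused log-variance head receives no gradient.
#'
#' @inheritParams vae
#' @return An object of class `c("autoencoder", "vae")`; all [vae()]
#'   methods apply, and encoding is always deterministic.
#' @seealso [ae_encode()]
#' @export
autoencoder <- function(x, architecture = NULL, latent_dim = 50L,
                        n_layers = 2L, loss = c("l1", "l2", "bce"),
                        epochs = 300L, batch_size = 64L,
                        learning_rate = 2e-3, beta1 = 0.9, beta2 = 0.999,
                        patience = 25L, n_restarts = 3L, seed = 1L,
                        verbose = FALSE) {
  if (is_feature_matrix(x)) assert_state(x, "minmax")
  xm <- if (is_feature_matrix(x)) fm_values(x) else as.matrix(x)
  if (any(xm < 0) || any(xm > 1))
    stop("'x' must be min-max scaled into [0, 1]")
  if (is.null(architecture))
    architecture <- vae_architecture("custom", input_dim = ncol(xm),
                                     latent_dim = latent_dim,
                                     n_layers = n_layers,
                                     loss = match.arg(loss))
  if (architecture$input_dim != ncol(xm))
    stop("architecture input_dim does not match data")
  fit <- train_net(xm, architecture, kl_weight = 0, sample_latent = FALSE,
                   epochs = epochs, batch_size = batch_size,
                   learning_rate = learning_rate, beta1 = beta1,
                   beta2 = beta2, patience = patience, seed = seed,
                   verbose = verbose, n_restarts = n_restarts)
  structure(list(params = fit$params, architecture = architecture,
                 training_log = fit$log, feature_ids = colnames(xm),
                 x = xm, kl_weight = 0, seed = as.integer(seed),
                 call = match.call()),
            class = c("autoencoder", "vae"))
}

#' @export
encode.autoencoder <- function(object, x, deterministic = TRUE, seed = 1L) {
  encode.vae(object, x, deterministic = TRUE, seed = seed)
}

#' Deterministic autoencoder code for samples
#'
#' @param object a fitted [autoencoder()].
#' @param x samples x features matrix in `[0, 1]`.
#' @return Matrix of latent codes (samples x h).
#' @export
ae_encode <- function(object, x) {
  if (!inherits(object, "autoencoder"))
    stop("'object' must be a fitted autoencoder")
  encode(object, x, deterministic = TRUE)$z
}
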