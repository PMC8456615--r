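# The variational autoencoder: probabilistic encoder (mu, variance),
# reparameterized sampling, configurable reconstruction loss (L1 / L2 /
# binary cross-entropy), closed-form Gaussian KL regularizer, and an Adam
# training loop. The encoder maps x in [0,1]^m to an h-dimensional Gaussian
# N(mu(x), diag(var(x))); the mirrored decoder maps z back to [0,1]^m
# through a sigmoid output layer.

#' Network architecture plan for a VAE or autoencoder
#'
#' Three named presets follow the published architectures: `"vae1"` (deep:
#' six encoder layers, latent dimension 50), `"vae2"` (shallow: two layers,
#' latent 400) and `"vae3"` (two layers, latent 500); the decoder always
#' mirrors the encoder. Hidden-layer widths are geometrically interpolated
#' between the input dimension and the latent dimension, so a preset is
#' fully reproducible from `(input_dim, latent_dim, n_layers)` alone. Both
#' `latent_dim` and `n_layers` may be overridden (e.g., a "vae1"-style deep
#' net with a small latent space for a small synthetic cohort).
#'
#' @param name `"vae1"`, `"vae2"`, `"vae3"` or `"custom"`.
#' @param input_dim number of input features m.
#' @param latent_dim latent dimension h; defaults to the preset's value.
#' @param n_layers number of dense layers in the encoder (the last one
#'   produces the `2h` outputs mu and log-variance); defaults to preset.
#' @param loss reconstruction loss: `"l1"` (default, the loss found best
#'   for this application), `"l2"`, or `"bce"`.
#' @param mc_samples J, number of latent noise draws averaged per gradient
#'   step (default 1).
#' @return A `vae_architecture` list with the resolved layer widths.
#' @export
vae_architecture <- function(name = c("vae1", "vae2", "vae3", "custom"),
                             input_dim, latent_dim = NULL, n_layers = NULL,
                             loss = c("l1", "l2", "bce"), mc_samples = 1L) {
  name <- match.arg(name)
  loss <- match.arg(loss)
  presets <- list(vae1 = list(h = 50L, layers = 6L),
                  vae2 = list(h = 400L, layers = 2L),
                  vae3 = list(h = 500L, layers = 2L))
  if (name != "custom") {
    if (is.null(latent_dim)) latent_dim <- presets[[name]]$h
    if (is.null(n_layers)) n_layers <- presets[[name]]$layers
  }
  if (is.null(latent_dim) || is.null(n_layers))
    stop("custom architecture needs explicit 'latent_dim' and 'n_layers'")
  latent_dim <- as.integer(latent_dim)
  n_layers <- as.integer(n_layers)
  if (latent_dim < 1L) stop("'latent_dim' must be >= 1")
  if (n_layers < 1L) stop("'n_layers' must be >= 1")
  if (mc_samples < 1L) stop("'mc_samples' must be >= 1")
  hidden <- if (n_layers > 1L)
    pmax(round(exp(seq(log(input_dim), log(latent_dim),
                       length.out = n_layers + 1L)))[2:n_layers],
         2L * latent_dim)
  else integer(0)
  structure(list(name = name, input_dim = as.integer(input_dim),
                 latent_dim = latent_dim, n_layers = n_layers,
                 hidden = as.integer(hidden), loss = loss,
                 mc_samples = as.integer(mc_samples)),
            class = "vae_architecture")
}

#' @export
print.vae_architecture <- function(x, ...) {
  cat(sprintf("vae_architecture '%s': %d -> [%s] -> h=%d (loss %s, J=%d)\n",
              x$name, x$input_dim,
              paste(x$hidden, collapse = ", "), x$latent_dim,
              toupper(x$loss), x$mc_samples))
  invisible(x)
}

#' Reparameterized latent draw
#'
#' Computes `z = mu + sqrt(var) * eps` elementwise; with `eps ~ N(0, I)`
#' this realizes a draw from `N(mu, diag(var))` while keeping the noise
#' source independent of the encoder parameters (the reparameterization
#' trick that makes the objective amenable to backpropagation).
#'
#' @param mu,var,eps numeric vectors (or matrices) of equal shape; `var`
#'   must be strictly positive.
#' @return `mu + sqrt(var) * eps`.
#' @examples
#' reparameterize(c(1, 2), c(4, 9), c(1, -1))  # c(3, -1)
#' @export
reparameterize <- function(mu, var, eps) {
  if (any(var <= 0)) stop("'var' must be strictly positive")
  if (length(mu) != length(var) || length(mu) != length(eps))
    stop("'mu', 'var' and 'eps' must have the same length")
  mu + sqrt(var) * eps
}

#' Reconstruction loss between an input and its decoded draws
#'
#' Averages, over one or more decoded draws, the p-norm discrepancy
#' `||x - xhat||_p^p` (p = 1 or 2) or the summed elementwise binary
#' cross-entropy.
#'
#' @param x numeric vector in `[0,1]^m`.
#' @param x_recon a numeric vector, or a list of vectors (one per latent
#'   draw), each in `[0,1]^m`.
#' @param loss `"l1"`, `"l2"` or `"bce"` (aliases `1`, `2` accepted).
#' @return Nonnegative scalar.
#' @examples
#' reconstruction_loss(c(0.2, 0.8), c(0.5, 0.5), "l1")  # 0.6
#' reconstruction_loss(c(0.2, 0.8), c(0.5, 0.5), "l2")  # 0.18
#' @export
reconstruction_loss <- function(x, x_recon, loss = c("l1", "l2", "bce")) {
  if (is.numeric(loss)) loss <- c("l1", "l2")[loss]
  loss <- match.arg(loss)
  if (!is.list(x_recon)) x_recon <- list(x_recon)
  vals <- vapply(x_recon, function(xh) {
    if (length(xh) != length(x)) stop("draw length does not match 'x'")
    if (loss == "bce" && (any(xh <= 0) || any(xh >= 1)))
      stop("BCE requires reconstructions strictly inside (0, 1)")
    sum(recon_value(matrix(x, 1), matrix(xh, 1), loss))
  }, numeric(1))
  mean(vals)
}

#' Closed-form KL divergence from N(mu, diag(var)) to N(0, I)
#'
#' The analytic Gaussian form `0.5 * sum(mu^2 + var - log(var) - 1)`,
#' nonnegative and zero exactly when `mu = 0`, `var = 1`.
#'
#' @param mu,var numeric vectors of equal length; `var > 0`.
#' @return Nonnegative scalar.
#' @examples
#' kl_closed_form(0, 1)            # 0
#' kl_closed_form(1, 1)            # 0.5
#' kl_closed_form(0, exp(1))       # (e - 2) / 2
#' @export
kl_closed_form <- function(mu, var) {
  if (any(var <= 0)) stop("'var' must be strictly positive")
  if (length(mu) != length(var)) stop("'mu' and 'var' lengths differ")
  0.5 * sum(mu^2 + var - log(var) - 1)
}

#' Norm-style regularizer variant (for comparison only)
#'
#' A regularizer sometimes written in VAE derivations,
#' `||mu||_2^2 + ||sigma||_2^2 - ||log(sigma)||_1 - 1`, which resembles
#' but is not the Gaussian KL divergence (it lacks the 1/2 factor, takes
#' an absolute value of the log term, and subtracts a scalar rather than
#' the latent dimension; it can even be negative). It is provided so the
#' discrepancy can be examined numerically; [kl_closed_form()] is what the
#' package trains with.
#'
#' @inheritParams kl_closed_form
#' @return Scalar (can be negative).
#' @export
kl_printed_form <- function(mu, var) {
  if (any(var <= 0)) stop("'var' must be strictly positive")
  sum(mu^2) + sum(var^2) - sum(abs(log(var))) - 1
}

build_eps <- function(b, h, J) lapply(seq_len(J), function(j)
  matrix(stats::rnorm(b * h), b, h))

#' Fit a variational autoencoder to min-max scaled expression data
#'
#' Minimizes, by minibatch Adam, the joint objective: the sum over samples
#' of the Monte-Carlo-averaged reconstruction loss plus the closed-form KL
#' divergence of the encoded Gaussian from the standard-normal prior. The
#' optimizer uses the published settings (learning rate 2e-3, beta1 0.9,
#' beta2 0.999); training stops early when the epoch objective plateaus.
#' Training is deterministic given `seed`.
#'
#' @param x a [feature_matrix()] in state `"minmax"` (or a plain numeric
#'   matrix with values in `[0, 1]`), samples x features.
#' @param architecture a [vae_architecture()]; alternatively leave `NULL`
#'   and give `latent_dim`/`n_layers`/`loss` directly.
#' @param latent_dim,n_layers,loss,mc_samples shortcut arguments used when
#'   `architecture` is `NULL` (defaults: h = 50, 2 layers, L1 loss, J = 1).
#' @param epochs maximum training epochs (default 300).
#' @param batch_size minibatch size (default 64).
#' @param learning_rate,beta1,beta2 Adam settings.
#' @param patience early-stopping patience on the training objective
#'   (epochs without improvement; default 25 -- with few Monte-Carlo draws
#'   the epoch objective is noisy, and a short patience stops training
#'   well before the latent space has organized).
#' @param kl_weight weight on the KL term (default 1; 0 gives a plain
#'   autoencoder objective).
#' @param kl_warmup epochs over which the KL weight is ramped linearly
#'   from 0 to its final value at the start of training (default 20).
#'   Warm-up is a standard optimization device against posterior collapse
#'   (the encoder locking onto the prior before the decoder has learned to
#'   use the latent space); the objective being minimized from
#'   `kl_warmup + 1` onwards is exactly the stated one.
#' @param n_restarts number of independent multi-start fits (default 3);
#'   the fit with the lowest final training objective is kept. The joint
#'   objective is non-convex and deep encoders occasionally stall in a
#'   poor basin; restarts make the fit reproducible *and* reliable.
#' @param seed integer RNG seed controlling initialization, batching and
#'   latent noise.
#' @param verbose print per-epoch objectives.
#' @return An object of class `"vae"` with components `params` (encoder
#'   and decoder weights), `architecture`, `training_log` (per-epoch
#'   objective, reconstruction and KL sums), `feature_ids`, `x` (training
#'   data), `kl_weight`, `seed`.
#' @seealso [encode()], [decode()], [autoencoder()]
#' @export
vae <- function(x, architecture = NULL, latent_dim = 50L, n_layers = 2L,
                loss = c("l1", "l2", "bce"), mc_samples = 1L,
                epochs = 300L, batch_size = 64L, learning_rate = 2e-3,
                beta1 = 0.9, beta2 = 0.999, patience = 25L,
                kl_weight = 1, kl_warmup = 20L, n_restarts = 3L,
                seed = 1L, verbose = FALSE) {
  if (is_feature_matrix(x)) assert_state(x, "minmax")
  xm <- if (is_feature_matrix(x)) fm_values(x) else as.matrix(x)
  if (any(xm < 0) || any(xm > 1))
    stop("'x' must be min-max scaled into [0, 1]")
  if (is.null(architecture))
    architecture <- vae_architecture("custom", input_dim = ncol(xm),
                                     latent_dim = latent_dim,
                                     n_layers = n_layers,
                                     loss = match.arg(loss),
                                     mc_samples = mc_samples)
  if (architecture$input_dim != ncol(xm))
    stop("architecture input_dim (", architecture$input_dim,
         ") does not match data (", ncol(xm), " features)")
  fit <- train_net(xm, architecture, kl_weight = kl_weight,
                   sample_latent = TRUE, epochs = epochs,
                   batch_size = batch_size, learning_rate = learning_rate,
                   beta1 = beta1, beta2 = beta2, patience = patience,
                   seed = seed, verbose = verbose, n_restarts = n_restarts,
                   kl_warmup = kl_warmup)
  structure(list(params = fit$params, architecture = architecture,
                 training_log = fit$log, feature_ids = colnames(xm),
                 x = xm, kl_weight = kl_weight, seed = as.integer(seed),
                 call = match.call()),
            class = "vae")
}

# shared trainer for vae() and autoencoder(); sample_latent = FALSE gives a
# deterministic bottleneck z = mu (no latent noise). The objective is
# non-convex; n_restarts independent fits are run from seeds derived from
# 'seed' and the one with the lowest final training objective is kept.
train_net <- function(xm, arch, kl_weight, sample_latent, epochs, batch_size,
                      learning_rate, beta1, beta2, patience, seed, verbose,
                      n_restarts = 3L, kl_warmup = 20L) {
  fits <- lapply(seq_len(n_restarts), function(r)
    train_net_once(xm, arch, kl_weight, sample_latent, epochs, batch_size,
                   learning_rate, beta1, beta2, patience,
                   seed + (r - 1L) * 101L, verbose, kl_warmup))
  finals <- vapply(fits, function(f) utils::tail(f$log$objective, 1),
                   numeric(1))
  best <- fits[[which.min(finals)]]
  best$restart_objectives <- finals
  best
}

train_net_once <- function(xm, arch, kl_weight, sample_latent, epochs,
                           batch_size, learning_rate, beta1, beta2, patience,
                           seed, verbose, kl_warmup = 0L) {
  n <- nrow(xm); m <- ncol(xm); h <- arch$latent_dim
  with_local_seed(seed, {
    enc <- init_mlp(c(m, arch$hidden, 2L * h))
    dec <- init_mlp(c(h, rev(arch$hidden), m))
    st_e <- list(m = adam_init(enc), v = adam_init(enc))
    st_d <- list(m = adam_init(dec), v = adam_init(dec))
    log_df <- data.frame(epoch = integer(0), objective = numeric(0),
                         recon = numeric(0), kl = numeric(0))
    best <- Inf; stall <- 0L; t_step <- 0L
    for (ep in seq_len(epochs)) {
      # KL warm-up: ramp the weight over the first kl_warmup epochs, then
      # hold it at kl_weight; early stopping only starts once the ramp is
      # over, so logged objectives being compared are of the same function
      w_ep <- if (kl_warmup > 0L && ep <= kl_warmup)
        kl_weight * ep / (kl_warmup + 1) else kl_weight
      ord <- sample.int(n)
      tot_obj <- tot_rec <- tot_kl <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- xm[idx, , drop = FALSE]
        eps <- if (sample_latent)
          build_eps(nrow(Xb), h, arch$mc_samples) else NULL
        lg <- vae_loss_grad(enc, dec, Xb, h, arch$loss, eps, w_ep)
        if (!is.finite(lg$objective))
          stop(sprintf("non-finite objective at epoch %d, batch starting %d",
                       ep, start))
        tot_obj <- tot_obj + lg$objective
        tot_rec <- tot_rec + lg$recon
        tot_kl <- tot_kl + lg$kl
        t_step <- t_step + 1L
        se <- adam_step(enc, lg$enc_grads, st_e, t_step, learning_rate,
                        beta1, beta2)
        enc <- se$params; st_e <- se$state
        sd_ <- adam_step(dec, lg$dec_grads, st_d, t_step, learning_rate,
                         beta1, beta2)
        dec <- sd_$params; st_d <- sd_$state
      }
      # log the full-weight objective so epochs are comparable
      full_obj <- tot_rec + kl_weight * tot_kl
      log_df <- rbind(log_df, data.frame(epoch = ep, objective = full_obj,
                                         recon = tot_rec, kl = tot_kl))
      if (verbose)
        message(sprintf("epoch %3d  objective %.4f", ep, full_obj))
      if (ep > kl_warmup) {
        if (!is.finite(best) || full_obj < best - 1e-6 * max(1, abs(best))) {
          best <- full_obj; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
    list(params = list(encoder = enc, decoder = dec), log = log_df)
  })
}

encoder_heads <- function(object, xm) {
  h <- object$architecture$latent_dim
  P <- mlp_forward(object$params$encoder, xm, final = "linear")$out
  mu <- P[, seq_len(h), drop = FALSE]
  lv <- pmin(pmax(P[, h + seq_len(h), drop = FALSE], -15), 15)
  list(mu = mu, var = exp(lv))
}

as_input_matrix <- function(object, x) {
  xm <- if (is_feature_matrix(x)) fm_values(x) else
    if (is.null(dim(x))) matrix(x, 1, dimnames = list("x1", names(x))) else
      as.matrix(x)
  if (ncol(xm) != object$architecture$input_dim)
    stop("input has ", ncol(xm), " features; model expects ",
         object$architecture$input_dim)
  xm
}

#' Encode samples into the latent space
#'
#' Returns the encoder's per-sample posterior mean `mu` and variance `var`,
#' plus a latent code `z`: a single reparameterized draw from
#' `N(mu, diag(var))` (the encoding used downstream for supervised
#' learning), or exactly `mu` in deterministic mode.
#'
#' @param object a fitted [vae()] (or [autoencoder()], which is always
#'   deterministic).
#' @param x samples x features matrix (or single profile) in `[0, 1]`.
#' @param deterministic if `TRUE`, `z = mu` (no sampling).
#' @param seed RNG seed for the draw (ignored when deterministic).
#' @return A `latent_encoding` list: matrices `mu`, `var`, `z`
#'   (samples x h).
#' @export
encode <- function(object, x, deterministic = FALSE, seed = 1L) {
  UseMethod("encode")
}

#' @export
encode.vae <- function(object, x, deterministic = FALSE, seed = 1L) {
  xm <- as_input_matrix(object, x)
  heads <- encoder_heads(object, xm)
  z <- if (deterministic) heads$mu else with_local_seed(seed, {
    heads$mu + sqrt(heads$var) *
      matrix(stats::rnorm(length(heads$mu)), nrow(heads$mu))
  })
  dimnames(z) <- list(rownames(xm),
                      paste0("Z", seq_len(ncol(z))))
  dimnames(heads$mu) <- dimnames(heads$var) <- dimnames(z)
  structure(list(mu = heads$mu, var = heads$var, z = z),
            class = "latent_encoding")
}

#' @export
print.latent_encoding <- function(x, ...) {
  cat(sprintf("latent_encoding: %d sample(s) x h=%d\n",
              nrow(x$mu), ncol(x$mu)))
  invisible(x)
}

#' Decode latent codes back to gene space
#'
#' @param object a fitted [vae()] or [autoencoder()].
#' @param z latent matrix (samples x h) or a single latent vector.
#' @return Matrix of reconstructions in `[0, 1]^m`.
#' @export
decode <- function(object, z) {
  if (!inherits(object, "vae")) stop("'object' must be a fitted vae/autoencoder")
  if (is.null(dim(z))) z <- matrix(z, 1)
  if (ncol(z) != object$architecture$latent_dim)
    stop("latent dimension mismatch: got ", ncol(z), ", expected ",
         object$architecture$latent_dim)
  out <- mlp_forward(object$params$decoder, z, final = "sigmoid")$out
  colnames(out) <- object$feature_ids
  out
}

#' Joint VAE objective for a data batch
#'
#' Sum over samples of reconstruction loss (Monte-Carlo averaged over
#' `mc_samples` draws) plus the closed-form KL regularizer, i.e. the
#' quantity the training loop minimizes.
#'
#' @param object a fitted [vae()].
#' @param x batch in `[0, 1]` (defaults to the training data).
#' @param seed RNG seed for the latent draws.
#' @param deterministic if `TRUE`, evaluate at `z = mu` (no noise).
#' @return Scalar objective value.
#' @export
vae_objective <- function(object, x = object$x, seed = 1L,
                          deterministic = FALSE) {
  xm <- as_input_matrix(object, x)
  h <- object$architecture$latent_dim
  eps <- if (deterministic) NULL else with_local_seed(seed,
    build_eps(nrow(xm), h, object$architecture$mc_samples))
  vae_loss_grad(object$params$encoder, object$params$decoder, xm, h,
                object$architecture$loss, eps, object$kl_weight)$objective
}

#' @export
print.vae <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("%s: %d features -> h=%d (%d encoder layers, %s loss)\n",
              if (inherits(x, "autoencoder")) "autoencoder" else
                "variational autoencoder",
              a$input_dim, a$latent_dim, a$n_layers, toupper(a$loss)))
  n_ep <- nrow(x$training_log)
  cat(sprintf("  trained %d epochs on %d samples; objective %.2f -> %.2f\n",
              n_ep, nrow(x$x), x$training_log$objective[1],
              x$training_log$objective[n_ep]))
  invisible(x)
}

#' @export
summary.vae <- function(object, ...) {
  res <- residuals(object)
  out <- list(architecture = object$architecture,
              n_samples = nrow(object$x),
              epochs = nrow(object$training_log),
              final_objective = utils::tail(object$training_log$objective, 1),
              final_recon = utils::tail(object$training_log$recon, 1),
              final_kl = utils::tail(object$training_log$kl, 1),
              mean_abs_residual = mean(abs(res)))
  class(out) <- "summary.vae"
  out
}

#' @export
print.summary.vae <- function(x, ...) {
  print(x$architecture)
  cat(sprintf("samples: %d   epochs: %d\n", x$n_samples, x$epochs))
  cat(sprintf("final objective: %.3f (recon %.3f + kl %.3f)\n",
              x$final_objective, x$final_recon, x$final_kl))
  cat(sprintf("mean |reconstruction residual|: %.4f\n", x$mean_abs_residual))
  invisible(x)
}

#' @describeIn vae latent encodings (`type = "latent"`, a sampled draw;
#'   `"mu"`, the posterior mean) or reconstructions
#'   (`type = "reconstruction"`).
#' @param object fitted model.
#' @param newdata matrix in `[0, 1]`; defaults to the training data.
#' @param type what to return.
#' @param ... unused.
#' @export
predict.vae <- function(object, newdata = object$x,
                        type = c("latent", "mu", "reconstruction"),
                        deterministic = FALSE, seed = 1L, ...) {
  type <- match.arg(type)
  enc <- encode(object, newdata, deterministic = deterministic ||
                  type == "mu" || inherits(object, "autoencoder"),
                seed = seed)
  switch(type,
         latent = enc$z,
         mu = enc$mu,
         reconstruction = decode(object, enc$z))
}

#' @export
residuals.vae <- function(object, newdata = object$x, ...) {
  xm <- as_input_matrix(object, newdata)
  xm - predict(object, xm, type = "reconstruction", deterministic = TRUE)
}

#' @export
coef.vae <- function(object, ...) object$params

#' @export
plot.vae <- function(x, ...) {
  tl <- x$training_log
  graphics::plot(tl$epoch, tl$objective, type = "l", xlab = "epoch",
                 ylab = "training objective",
                 main = "VAE training trajectory", ...)
  graphics::lines(tl$epoch, tl$recon, lty = 2)
  graphics::legend("topright", legend = c("objective", "reconstruction"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' @export
simulate.vae <- function(object, nsim = 1, seed = NULL, ...) {
  h <- object$architecture$latent_dim
  draw <- function() decode(object,
                            matrix(stats::rnorm(nsim * h), nsim, h))
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}
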