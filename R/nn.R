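# Minimal fully-connected network machinery used by the VAE and the plain
# autoencoder: He-initialized dense layers, ReLU hidden activations, manual
# backpropagation, and an Adam optimizer. Everything is plain matrix
# algebra on samples-in-rows batches; networks at the package's scale (a
# few hundred inputs) train in seconds on one CPU.

init_mlp <- function(widths) {
  lapply(seq_len(length(widths) - 1L), function(i) {
    n_in <- widths[i]; n_out <- widths[i + 1L]
    list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                    n_in, n_out),
         b = rep(0, n_out))
  })
}

# leaky rectifier: small negative slope keeps deep encoders from
# accumulating dead units under the fixed 2e-3 learning rate
leaky_slope <- 0.01
relu <- function(x) ifelse(x > 0, x, leaky_slope * x)
relu_grad <- function(pre) ifelse(pre > 0, 1, leaky_slope)

# forward pass; final activation "linear" or "sigmoid"; returns output and
# the per-layer inputs/pre-activations needed for backprop
mlp_forward <- function(layers, X, final = c("linear", "sigmoid")) {
  final <- match.arg(final)
  L <- length(layers)
  inputs <- vector("list", L)
  pre <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    inputs[[l]] <- H
    A <- H %*% layers[[l]]$W + matrix(layers[[l]]$b, nrow(H),
                                      length(layers[[l]]$b), byrow = TRUE)
    pre[[l]] <- A
    H <- if (l < L) relu(A) else if (final == "sigmoid") stats::plogis(A) else A
  }
  list(out = H, inputs = inputs, pre = pre)
}

# backprop from the gradient w.r.t. the FINAL PRE-ACTIVATION (d_pre);
# returns per-layer gradients and the gradient w.r.t. the network input
mlp_backward <- function(layers, cache, d_pre) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- d_pre
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(cache$inputs[[l]], delta),
                       b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(layers[[l]]$W)) * relu_grad(cache$pre[[l - 1L]])
  }
  list(grads = grads, d_input = delta %*% t(layers[[1L]]$W))
}

adam_init <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

adam_step <- function(params, grads, state, t, lr = 2e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(params)) {
    for (nm in c("W", "b")) {
      r <- upd(params[[l]][[nm]], grads[[l]][[nm]],
               state$m[[l]][[nm]], state$v[[l]][[nm]])
      params[[l]][[nm]] <- r$p
      state$m[[l]][[nm]] <- r$m
      state$v[[l]][[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}

# gradient of the reconstruction term w.r.t. the decoder's final
# pre-activation (sigmoid output layer), per loss kind
recon_dlogits <- function(x, xhat, loss) {
  switch(loss,
         l1 = sign(xhat - x) * xhat * (1 - xhat),
         l2 = 2 * (xhat - x) * xhat * (1 - xhat),
         bce = xhat - x,
         stop("unknown loss kind: ", loss))
}

recon_value <- function(x, xhat, loss) {
  switch(loss,
         l1 = rowSums(abs(x - xhat)),
         l2 = rowSums((x - xhat)^2),
         bce = {
           xh <- pmin(pmax(xhat, 1e-7), 1 - 1e-7)
           rowSums(-(x * log(xh) + (1 - x) * log(1 - xh)))
         },
         stop("unknown loss kind: ", loss))
}

# joint objective and gradients for one batch, with the latent noise draws
# supplied explicitly (a list of J matrices, or NULL for a deterministic
# bottleneck z = mu). Returns the summed-over-batch objective and gradients
# of the per-sample MEAN objective (what the optimizer steps on).
vae_loss_grad <- function(enc, dec, X, h, loss, eps_list, kl_weight = 1) {
  b <- nrow(X)
  ef <- mlp_forward(enc, X, final = "linear")
  P <- ef$out
  mu <- P[, seq_len(h), drop = FALSE]
  lv <- pmin(pmax(P[, h + seq_len(h), drop = FALSE], -15), 15)
  sd_ <- exp(0.5 * lv)
  deterministic <- is.null(eps_list)
  if (deterministic) eps_list <- list(matrix(0, b, h))
  J <- length(eps_list)

  d_mu <- matrix(0, b, h)
  d_lv <- matrix(0, b, h)
  dec_grads <- NULL
  recon_sum <- numeric(b)
  for (j in seq_len(J)) {
    z <- mu + sd_ * eps_list[[j]]
    df <- mlp_forward(dec, z, final = "sigmoid")
    xhat <- df$out
    recon_sum <- recon_sum + recon_value(X, xhat, loss)
    dlog <- recon_dlogits(X, xhat, loss) / J
    bk <- mlp_backward(dec, df, dlog)
    dec_grads <- if (is.null(dec_grads)) bk$grads else
      mapply(function(a, g) list(W = a$W + g$W, b = a$b + g$b),
             dec_grads, bk$grads, SIMPLIFY = FALSE)
    dz <- bk$d_input
    d_mu <- d_mu + dz
    if (!deterministic)
      d_lv <- d_lv + dz * eps_list[[j]] * 0.5 * sd_
  }
  recon <- recon_sum / J
  kl <- 0.5 * rowSums(mu^2 + exp(lv) - lv - 1)
  if (kl_weight != 0) {
    d_mu <- d_mu + kl_weight * mu
    d_lv <- d_lv + kl_weight * 0.5 * (exp(lv) - 1)
  }
  dP <- cbind(d_mu, d_lv) / b        # mean-per-sample gradient scale
  dec_grads <- rapply(dec_grads, function(g) g / b, how = "replace")
  enc_grads <- mlp_backward(enc, ef, dP)$grads
  list(objective = sum(recon + kl_weight * kl),
       recon = sum(recon), kl = sum(kl),
       enc_grads = enc_grads, dec_grads = dec_grads)
}
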