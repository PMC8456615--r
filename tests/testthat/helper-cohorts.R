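# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small labeled cohort for labeling / preprocessing / classification tests
small_cohort <- function() cached("small_cohort",
  generate_cohort(synthetic_spec(n_types = 2L, samples_per_type = 30L,
                                 n_genes = 80L, latent_dim_true = 4L,
                                 labeled_fraction = 0.5, seed = 101L)))

# preprocessed features of the small cohort
small_features <- function() cached("small_features", {
  co <- small_cohort()
  preprocess_cohort(co$counts, co$abundance, group = co$type_of)$features
})

# a trained small VAE shared across method tests
small_vae <- function() cached("small_vae",
  vae(small_features(), latent_dim = 4L, n_layers = 2L, epochs = 80L,
      n_restarts = 1L, seed = 5L))

# random matrix in [0,1] with dimnames, for encoder input contracts
runif_minmax <- function(n, m, seed = 1L) {
  set.seed(seed)
  matrix(runif(n * m), n, m,
         dimnames = list(sprintf("s%03d", seq_len(n)),
                         sprintf("f%03d", seq_len(m))))
}

# brute-force AUROC over all positive-negative pairs (independent oracle)
auroc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force MAD oracle: median absolute deviation from the median
mad_brute <- function(v) 1.4826 * median(abs(v - median(v)))

# Monte-Carlo KL( N(mu, diag(var)) || N(0, I) ) by sampling
kl_monte_carlo <- function(mu, var, n_draws = 1e5, seed = 1L) {
  set.seed(seed)
  h <- length(mu)
  z <- matrix(rnorm(n_draws * h), n_draws, h)
  z <- sweep(sweep(z, 2, sqrt(var), `*`), 2, mu, `+`)
  logq <- -0.5 * rowSums(sweep(sweep(z, 2, mu, `-`)^2, 2, var, `/`)) -
    0.5 * sum(log(2 * pi * var))
  logp <- -0.5 * rowSums(z^2) - 0.5 * h * log(2 * pi)
  mean(logq - logp)
}

# adjusted Rand index between two partitions (closed form on the
# contingency table; independent of any clustering package)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  e1 <- sum_comb(rowSums(tab)); e2 <- sum_comb(colSums(tab))
  expected <- e1 * e2 / choose(n, 2)
  maxi <- (e1 + e2) / 2
  if (maxi == expected) return(1)
  (idx - expected) / (maxi - expected)
}
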