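# tumorvae

Semi-supervised prediction of tumor response to chemotherapy from bulk
RNA-seq transcriptomes. Most public tumor transcriptomes carry no clinical
response annotation; `tumorvae` uses *all* of them anyway: a variational
autoencoder (VAE) is fit unsupervised to every profile, and a
gradient-boosted tree classifier (XGBoost) is then trained on the latent
encodings of the clinically labeled subset. The package is aimed at
computational oncology groups who want to benchmark latent-feature
classifiers for response prediction — and at anyone who needs the
surrounding machinery: robust variance filtering of genes, clinical label
parsing, and a replicated cross-validation harness with honest statistics.

## The model

Each tumor's expression profile is reduced to the top 20% most variable
genes (per cancer type, by median absolute deviation of FPKM-like
abundance, union across types), log2 total-count normalized and min-max
scaled into `x ∈ [0,1]^m`. A probabilistic encoder maps `x` to an
`h`-dimensional Gaussian `N(μ(x), diag σ²(x))`, `h ≪ m`; a mirrored
decoder `g` maps latent codes back to `[0,1]^m`. Training minimizes, over
all tumors,

    Σ_t [ (1/J) Σ_j ‖x_t − g(μ(x_t) + √σ²(x_t) ⊙ ε_j)‖_p^p
          + ½ Σ_i (μ_i² + σ_i² − log σ_i² − 1) ]

with `ε_j ~ N(0, I)` (the reparameterization trick) and `p = 1` by
default. The latent code of each labeled tumor — one sampled draw, or
deterministically `μ(x)` — is the feature vector for a tuned XGBoost
classifier of the binary label (0 = responded, 1 = progressive disease).
Baseline encoders (plain autoencoder, PCA at 90% variance, FastICA with
the PCA-matched component count) and comparator classifiers (kernel SVM,
KNN) are included, as are the published architecture presets (`vae1`:
six layers, h = 50; `vae2`: two layers, h = 400; `vae3`: two layers,
h = 500).

Performance is measured by replicated stratified five-fold
cross-validation with pooled out-of-fold scores — one AUROC and one AUPRC
per replication — and feature sets are compared by two-tailed Welch tests
on logit-transformed replication values.

A bundled synthetic-cohort generator (`generate_cohort()`) reproduces the
structure the method assumes — latent cancer-type clusters, a nonlinear
map to overdispersed counts, a partially labeled cohort with a controlled
class-balance ratio, and a response signal carried by a few latent
directions — so the whole pipeline runs and is tested without downloading
anything.

## Worked example

```r
library(tumorvae)

co <- generate_cohort(synthetic_spec(n_types = 2, samples_per_type = 100,
                                     n_genes = 200, seed = 42))
co
#> synthetic_cohort: 200 samples, 200 genes, 2 type clusters
#>   labeled: 67 (33.5%), responded/progressive = 46/21

study <- run_response_study(co, methods = c("raw", "vae", "pca"),
                            scheme = cv_scheme(replications = 5, seed_base = 1),
                            grid = hyper_grid("gbdt", n = 25),
                            latent_dim = 8, seed = 1)
study$table
#> comparison_table (reference: vae )
#>   method mean_auroc mean_auprc p_auroc_vs_ref p_auprc_vs_ref  best  tied
#> 1    raw     0.8382     0.6610        0.59400          0.128  TRUE FALSE
#> 2    vae     0.8303     0.6118             NA             NA FALSE FALSE
#> 3    pca     0.7594     0.5633        0.00109          0.203 FALSE FALSE
```

Reading the table: each `mean_auroc` is the average over five replications
of pooled-out-of-fold AUROC for that feature set; `p_auroc_vs_ref` is the
logit-scale Welch p-value against the VAE features. On this small, easy
cohort the 8-dimensional VAE encoding carries essentially the full signal
of the 200-gene profile (0.830 vs 0.838, not distinguishable at n = 5
replications) and clearly beats PCA components (p ≈ 0.001) — the
advantage of a *nonlinear* low-dimensional embedding.

A command-line wrapper over the same functions ships in
`inst/cli/tumorvae` (subcommands `simulate`, `train-vae`, `encode`,
`evaluate`).

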