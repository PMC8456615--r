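---
title: "Semi-supervised VAE features for chemotherapy response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised VAE features for chemotherapy response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the method

Most tumor transcriptomes in public cohorts carry no clinical annotation of
whether the patient's disease responded to chemotherapy; the labeled subset
is typically 5-15 times smaller than the full cohort, while the feature
space (genes) is in the tens of thousands. Fully supervised classifiers
trained on the labeled subset alone are starved for examples. `tumorvae`
implements a semi-supervised alternative in three steps:

1. **Unsupervised embedding.** A variational autoencoder (VAE) is fit to the
   min-max scaled, log-transformed expression profiles of *all* tumors,
   labeled and unlabeled, compressing each profile $x \in [0,1]^m$ into an
   $h$-dimensional latent Gaussian with mean $\mu(x)$ and diagonal variance
   $\sigma^2(x)$, $h \ll m$.
2. **Encoding the labeled subset.** Each clinically labeled tumor's latent
   code $z = \mu(x) + \sqrt{\sigma^2(x)} \odot \varepsilon$,
   $\varepsilon \sim N(0, I)$ (a single draw, or deterministically $z =
   \mu(x)$), becomes its feature vector.
3. **Supervised classification.** Gradient-boosted decision trees
   (XGBoost), tuned by grid search with inner five-fold cross-validation,
   predict the binary response label (0 = responded, 1 = progressive
   disease) from the latent codes. Kernel SVM and $k$-nearest-neighbors
   comparators are provided with their own published tuning grids.

Performance is measured by replicated stratified $k$-fold cross-validation:
within each replication every labeled tumor is scored exactly once, from
the fold where it was in the test set; the pooled out-of-fold scores give
one AUROC and one AUPRC per replication. Feature sets (raw expression, VAE,
plain autoencoder, PCA, ICA) are contrasted by two-tailed Welch tests on
logit-transformed replication values.

## The VAE objective

For each tumor $t$ the training objective is
$$
\frac{1}{J}\sum_{j=1}^{J}\big\lVert x_t - g_\phi\big(\mu_\theta(x_t) +
\sqrt{\sigma^2_\theta(x_t)}\,\varepsilon_j\big)\big\rVert_p^p
\;+\; D_{\mathrm{KL}}\!\big(N(\mu_\theta(x_t),
\mathrm{diag}\,\sigma^2_\theta(x_t))\,\Vert\,N(0, I)\big),
$$
summed over tumors and minimized jointly over encoder weights $\theta$ and
decoder weights $\phi$. The reconstruction norm is configurable: $p = 1$
(the default — empirically the best choice for this application), $p = 2$,
or elementwise binary cross-entropy. The KL term uses the standard Gaussian
closed form
$\tfrac12 \sum_i (\mu_i^2 + \sigma_i^2 - \log \sigma_i^2 - 1)$.
A norm-style variant of the regularizer that circulates in some derivations
($\lVert\mu\rVert_2^2 + \lVert\sigma\rVert_2^2 -
\lVert\log\sigma\rVert_1 - 1$) is exposed as `kl_printed_form()` for
comparison only; it is not the divergence of the stated Gaussians (it can
be negative, and at the prior it equals $h - 1$, not zero), which the test
suite demonstrates against a Monte-Carlo KL estimate.

The encoder network outputs log-variances; exponentiation guarantees
$\sigma^2 > 0$, and the square root enters only through the
reparameterized draw. We treat $\sigma(\cdot)$ as a *variance* vector
throughout, which is the reading consistent with the sampling law
$Z \sim N(\mu, \mathrm{diag}\,\sigma)$.

## Architectures

Three named presets mirror the published designs: `vae1` (six encoder
layers, $h = 50$), `vae2` (two layers, $h = 400$), `vae3` (two layers,
$h = 500$); the decoder always mirrors the encoder, and the final decoder
activation is a sigmoid so reconstructions live in $[0,1]^m$ as the input
contract requires (and as BCE loss needs). Only depth and $h$ are fixed by
the presets; hidden widths are geometrically interpolated between $m$ and
$h$ (floored at $2h$), making every architecture reproducible from
$(m, h, \text{layers})$ alone. Both $h$ and the layer count can be
overridden, e.g. a `vae1`-style deep net with $h = 8$ for a small
synthetic cohort.

# Preprocessing

* **Variance filter.** Genes are ranked per cancer type by the median
  absolute deviation (MAD) of their FPKM-like abundance across tumors, and
  the top 20% per type (ties at the boundary kept inclusively) are merged
  across types; the union is ordered lexicographically for a reproducible
  feature order. Abundances, not counts, drive the filter to mitigate
  gene-length and depth bias. The MAD uses the consistency constant 1.4826
  (the default of `stats::mad`); scores are rank-equivalent either way, so
  the constant cannot change which genes are selected.
* **Normalization.** Counts are divided by the per-sample total, rescaled
  to the cohort median library size, and transformed as $\log_2(1 + C)$.
  Any fixed target depth preserves the method; the median is chosen so the
  transformed values sit in a familiar range.
* **Scaling.** Min-max parameters are fitted per feature on the *full*
  cohort (labeled + unlabeled) — deliberately transductive, mirroring the
  semi-supervised use of all transcriptomes — and reused downstream.
  Values outside the reference range clip to $[0,1]$; features constant in
  the reference map to 0 (they carry no signal, and this avoids a division
  by zero).

# Optimization choices

The optimizer is Adam with the published settings (learning rate
$2\times10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$), minibatches of 64,
at most 300 epochs with early stopping after 25 epochs without improvement
of the epoch objective. With few Monte-Carlo draws the epoch objective is
noisy; a short patience systematically stops training before the latent
space has organized, which is why the patience is generous. Three further
choices matter in practice:

* **Leaky ReLU hidden activations** (slope 0.01). The deep six-layer
  preset under a fixed learning rate is prone to accumulating dead units
  with hard ReLUs.
* **KL warm-up.** The KL weight ramps linearly from 0 to 1 over the first
  20 epochs. Without it, some initializations collapse to the prior (KL
  $\approx 0$, the decoder reproducing the cohort mean) and never recover.
  The ramp is an optimizer schedule only: from epoch 21 the minimized
  objective is exactly the stated one, and the logged objective is always
  reported at full KL weight so epochs are comparable.
* **Multi-start.** The objective is non-convex; `n_restarts = 3`
  independent fits are run from derived seeds and the one with the lowest
  final training objective is kept. This makes fits both deterministic
  (given the seed) and reliable.

Monte-Carlo draws per gradient step default to $J = 1$. A published
analysis sets $J = m$; that choice multiplies the cost of every step by
the transcriptome dimension for a variance reduction that minibatching
already provides, so the package defaults to 1 and leaves $J$
configurable.

Batch normalization is deliberately omitted: at the network sizes this
package targets it adds running-moment state and couples a sample's
gradient to its minibatch for no measured benefit, and determinism across
batch-size choices is worth more here.

# The synthetic cohort generator

`generate_cohort()` produces the statistical structure the method assumes,
so every stage is testable without any external download:

* cancer-type clusters as Gaussian components in a $k$-dimensional latent
  space (cluster centers drawn with spread 2, within-cluster standard
  deviation 0.5 by default);
* a fixed random affine-plus-softplus map from latent space to nonnegative
  gene intensities, scaled by lognormal per-gene factors and per-sample
  library sizes;
* negative binomial counts (dispersion 10) — RNA-seq counts are
  overdispersed, and no downstream stage models counts generatively, so
  the exact family is free;
* an FPKM-like abundance matrix derived from the counts with random
  per-gene lengths, so the abundance-based filter path is exercised on a
  genuinely different matrix than the count path;
* binary response labels from a logistic model on a few designated latent
  directions, with the intercept solved numerically so the expected
  responding/progressive ratio among labeled samples hits the requested
  class-balance ratio; only a fixed fraction of samples reveals its label.

The defaults — three clusters of 200 tumors, 400 genes, a third of samples
labeled, balance ratio 2, standardized signal strength 2 — are the
conditions used by the package's own study-scale checks, and sit inside
the ranges reported for real five-cancer TCGA cohorts (labeled proportions
roughly 0.23–0.63, balance ratios 0.77–8.6, cohort sizes in the hundreds
per cancer type).

What the generator does *not* emulate: batch effects, gene–gene
correlation beyond the latent factor structure, read-level artifacts, or
drug heterogeneity. Passing tests on synthetic cohorts therefore
demonstrate that the machinery is correct and that the method recovers
signal of the assumed form; they do not certify performance on real tumor
data.

# Clinical labeling rules

Two annotation dialects are parsed. Xena-style rows label a tumor
*responded* when `measure_of_response` is complete or partial response and
*progressive* when it is radiographic/clinical progressive disease or
stable disease, in both cases only when `therapy_type` is chemotherapy.
cBioPortal-style rows use `Disease.Free.Status` (disease-free vs
recurred/progressed) gated by `Pharmaceutical.Therapy.Indicator = Yes` —
the schema's own chemotherapy marker, since the dialect has no therapy-type
text column. Matching is case-insensitive on trimmed, whitespace-collapsed
values ("Disease Free" and "DiseaseFree" both match). When records for the
same tumor disagree, progression wins: for a treatment-decision label the
conservative reading of conflicting evidence is the unfavorable one. These
merge rules are this package's documented choice; sources differ in how
they resolve such conflicts.

# Classifier tuning

The published gradient-boosted-tree grid (eight hyperparameters; tree
count 1–40, depth 1–10, six learning rates, and so on, with `gamma = 0`
fixed) has on the order of $10^8$–$10^9$ points; enumerating it per
training fold is not computationally plausible. The default budget is
therefore `random_n`: $n$ seeded draws from the grid (1000 by default, 50
in the study-scale checks), deduplicated with a stable order so a
duplicated point behaves exactly like a singleton; an exhaustive mode
remains available for reduced grids. The inner-CV selection metric is
AUROC — the tuning objective is not otherwise pinned down, and AUROC is
what the comparisons report. SVM scores use Platt-style probability
outputs so AUPRC is well defined across classifiers; the KNN comparator
implements Minkowski-$p$ distances and distance weighting directly, since
those grid axes must actually change predictions.

Feature importance for tree ensembles is cover-based (the share of
observations affected by splits on each feature), summed across
replications; never-used features report zero.

# Evaluation machinery

* **Stratified folds by default.** With class-balance ratios up to ~8.6,
  unstratified five-fold splits of a small labeled set frequently produce
  single-class test folds, where neither metric is defined; stratification
  is the only workable reading. Unstratified mode exists and fails loudly
  with advice when a fold degenerates.
* **AUROC** is the Mann–Whitney rank statistic with midrank tie handling
  (ties count ½), verified against brute-force pair enumeration to 1e-12
  and against an independent ROC implementation.
* **AUPRC** integrates the stepwise precision–recall curve by trapezoid,
  one point per distinct threshold (descending). The recall-0 anchor uses
  the precision at the highest threshold rather than the conventional 1:
  under that convention an all-tied (scoreless) classifier scores exactly
  the class prevalence and random scores average to prevalence, the
  behavior one wants from a chance baseline. (Anchoring at 1 inflates the
  all-tied case to $(1+\pi)/2$.)
* **Welch comparisons on the logit scale.** Replication AUROC/AUPRC values
  are clipped to $[10^{-3}, 1 - 10^{-3}]$ before the logit so a perfect
  replication cannot produce an infinity; identical or zero-variance
  groups return $p = 1$ with a degeneracy flag instead of erroring.
* **Replication seeds** are `seed_base + r`, so a scheme is reproducible
  from two integers.
* **2-D embedding diagnostics** (t-SNE: PCA initialization, perplexity 20,
  learning rate 300, 400 iterations; UMAP: 50 neighbors, minimum distance
  0.3, Euclidean metric) delegate to the reference implementations —
  scikit-learn and umap-learn, driven through a bundled Python helper —
  because no R implementation of either is part of this package's
  dependency set and these are the tools the settings were defined for.

# Problem sizes used in the package's own checks

The test suite and the acceptance script run entirely on synthetic
cohorts: 150 samples x 300 genes for the cluster-preservation check (deep
`vae1`-style net, $h = 8$); 600 samples (200 labeled, balance ratio 2) for
the signal-recovery study with five replications of five-fold CV and a
50-draw tuning budget per fold; twenty 200-sample null cohorts for the
calibration of the comparison harness; and 100–200 random instances for
each numerical oracle (KL vs Monte-Carlo at $10^5$ draws, AUROC and MAD vs
brute force). These sizes were chosen so the full pipeline — including
hyperparameter search inside every training fold — runs comfortably on a
single CPU while keeping every stage statistically meaningful.

# Known limitations

* The KL Monte-Carlo oracle band (0.01 at $10^5$ draws) is honest only for
  moderate posteriors; for extreme $(\mu, \sigma^2)$ the estimator's own
  standard error exceeds the band, so the oracle draws posteriors from the
  regime the prior term actually keeps encoders in.
* Real-data effects outside the generator's model (batch structure,
  drug-specific response, covariance beyond the factor structure) are
  untested by construction.
* The plain autoencoder is implemented as the VAE with KL weight zero and
  a deterministic bottleneck, which guarantees the two differ only by the
  KL/sampling terms but also means the comparison shares one codebase.
* Grid-search "exhaustiveness" is a budget choice, not a claim about any
  published run.
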