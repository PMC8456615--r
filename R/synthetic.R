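# Synthetic cohorts with the latent structure the semi-supervised method
# assumes: cancer-type clusters in a low-dimensional latent space, a fixed
# random nonlinear map up to nonnegative gene space, overdispersed counts,
# and a partially labeled response signal carried by a few latent directions.

#' Specification for a synthetic tumor cohort
#'
#' Defaults describe the cohort used throughout the package's own studies:
#' three cancer-type clusters of 200 tumors each (600 total), 400 genes, an
#' 8-dimensional true latent space, one third of samples clinically labeled
#' and a responding/progressive class-balance ratio of 2 -- sizes and rates
#' in the range reported for real five-cancer TCGA cohorts (labeled
#' proportions roughly 0.23-0.63, balance ratios roughly 0.77-8.6).
#'
#' @param n_types number of cancer-type clusters.
#' @param samples_per_type tumors per cluster.
#' @param n_genes number of genes (m).
#' @param latent_dim_true dimension of the generative latent space (k_true).
#' @param labeled_fraction fraction of samples carrying a clinical label,
#'   in (0, 1].
#' @param balance_ratio target responding/progressive ratio (> 0) among
#'   labeled samples, in expectation.
#' @param signal_dims number of latent directions carrying response signal
#'   (<= `latent_dim_true`).
#' @param signal_strength standardized effect size (>= 0) of the latent
#'   signal on the log-odds of progression; 0 means labels carry no signal.
#' @param noise_sd within-cluster standard deviation of the latent
#'   coordinates.
#' @param dispersion negative binomial size parameter for counts.
#' @param seed integer RNG seed; the cohort is a pure function of the spec.
#' @return A `synthetic_spec` object (validated list).
#' @seealso [generate_cohort()]
#' @export
synthetic_spec <- function(n_types = 3L, samples_per_type = 200L,
                           n_genes = 400L, latent_dim_true = 8L,
                           labeled_fraction = 1 / 3, balance_ratio = 2,
                           signal_dims = 2L, signal_strength = 2,
                           noise_sd = 0.5, dispersion = 10, seed = 1L) {
  spec <- list(n_types = as.integer(n_types),
               samples_per_type = as.integer(samples_per_type),
               n_genes = as.integer(n_genes),
               latent_dim_true = as.integer(latent_dim_true),
               labeled_fraction = labeled_fraction,
               balance_ratio = balance_ratio,
               signal_dims = as.integer(signal_dims),
               signal_strength = signal_strength,
               noise_sd = noise_sd,
               dispersion = dispersion,
               seed = as.integer(seed))
  for (f in c("n_types", "samples_per_type", "n_genes", "latent_dim_true",
              "signal_dims"))
    if (!is.finite(spec[[f]]) || spec[[f]] < 1L)
      stop("invalid synthetic_spec: '", f, "' must be a count >= 1")
  if (!is.finite(spec$labeled_fraction) ||
      spec$labeled_fraction <= 0 || spec$labeled_fraction > 1)
    stop("invalid synthetic_spec: 'labeled_fraction' must be in (0, 1]")
  if (!is.finite(spec$balance_ratio) || spec$balance_ratio <= 0)
    stop("invalid synthetic_spec: 'balance_ratio' must be > 0")
  if (spec$signal_dims > spec$latent_dim_true)
    stop("invalid synthetic_spec: 'signal_dims' must be <= 'latent_dim_true'")
  if (!is.finite(spec$signal_strength) || spec$signal_strength < 0)
    stop("invalid synthetic_spec: 'signal_strength' must be >= 0")
  if (!is.finite(spec$noise_sd) || spec$noise_sd < 0)
    stop("invalid synthetic_spec: 'noise_sd' must be >= 0")
  if (!is.finite(spec$dispersion) || spec$dispersion <= 0)
    stop("invalid synthetic_spec: 'dispersion' must be > 0")
  structure(spec, class = "synthetic_spec")
}

# run code under a temporary RNG state, restoring the caller's stream
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Generate a synthetic tumor cohort
#'
#' Per-sample latent vectors are drawn around cluster-specific Gaussian
#' means; a fixed random affine map followed by a softplus produces
#' nonnegative gene-space intensities, which are scaled to per-sample
#' library sizes and realized as negative binomial counts. An FPKM-like
#' abundance matrix is derived from the counts with random per-gene
#' "lengths" so that variance filtering on abundances is exercised on a
#' genuinely different matrix than the count path. Binary response labels
#' (0 responded / 1 progressive) follow a logistic model on the designated
#' signal latent directions, with the intercept solved numerically so the
#' expected responding/progressive ratio among labeled samples matches
#' `balance_ratio`; only a `labeled_fraction` subset of samples reveals its
#' label.
#'
#' @param spec a [synthetic_spec()].
#' @return A `synthetic_cohort` list: `counts` and `abundance`
#'   ([feature_matrix()] objects, samples x genes), `type_of` (named integer
#'   cluster ids), `label_of` (named; `0`, `1` or `NA` for unlabeled),
#'   `latent_truth` (samples x k_true matrix), and `spec`.
#' @examples
#' co <- generate_cohort(synthetic_spec(n_types = 2, samples_per_type = 20,
#'                                      n_genes = 50, seed = 7))
#' table(co$type_of)
#' table(co$label_of, useNA = "ifany")
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  n <- spec$n_types * spec$samples_per_type
  m <- spec$n_genes
  k <- spec$latent_dim_true
  with_local_seed(spec$seed, {
    sample_ids <- sprintf("S%04d", seq_len(n))
    gene_ids <- sprintf("G%04d", seq_len(m))
    type_of <- rep(seq_len(spec$n_types), each = spec$samples_per_type)

    # latent space: well-separated cluster means, isotropic within-cluster noise
    centers <- matrix(stats::rnorm(spec$n_types * k, sd = 2), spec$n_types, k)
    latent <- centers[type_of, , drop = FALSE] +
      matrix(stats::rnorm(n * k, sd = spec$noise_sd), n, k)
    dimnames(latent) <- list(sample_ids, paste0("L", seq_len(k)))

    # fixed nonlinear map to nonnegative gene intensities
    A <- matrix(stats::rnorm(k * m, sd = 1 / sqrt(k)), k, m)
    b <- stats::rnorm(m)
    gene_scale <- stats::rlnorm(m, meanlog = log(5), sdlog = 1)
    intensity <- sweep(softplus(latent %*% A +
                                  matrix(b, n, m, byrow = TRUE)),
                       2, gene_scale, `*`)

    # library sizes and overdispersed counts
    lib <- stats::rlnorm(n, meanlog = log(50 * m), sdlog = 0.3)
    prob_gs <- intensity / rowSums(intensity)
    mu <- prob_gs * lib
    counts <- matrix(stats::rnbinom(n * m, mu = mu, size = spec$dispersion),
                     n, m, dimnames = list(sample_ids, gene_ids))

    # FPKM-like abundances: counts per kilobase per million mapped reads
    len_kb <- stats::rlnorm(m, meanlog = log(1.5), sdlog = 0.7)
    depth_m <- pmax(rowSums(counts), 1) / 1e6
    abundance <- sweep(sweep(counts, 2, len_kb, `/`), 1, depth_m, `/`)

    # response labels: logistic on the signal latent directions
    raw <- rowSums(latent[, seq_len(spec$signal_dims), drop = FALSE])
    score <- if (spec$signal_strength > 0 && stats::sd(raw) > 0)
      spec$signal_strength * (raw - mean(raw)) / stats::sd(raw)
    else rep(0, n)
    target_p1 <- 1 / (1 + spec$balance_ratio)  # P(y = 1), progressive
    intercept <- stats::uniroot(function(c0) mean(stats::plogis(c0 + score)) -
                                  target_p1,
                                interval = c(-30, 30))$root
    y_all <- stats::rbinom(n, 1L, stats::plogis(intercept + score))

    n_labeled <- round(spec$labeled_fraction * n)
    labeled_idx <- sort(sample.int(n, n_labeled))
    label_of <- rep(NA_integer_, n)
    label_of[labeled_idx] <- y_all[labeled_idx]

    names(type_of) <- names(label_of) <- sample_ids
    structure(list(counts = feature_matrix(counts, "counts"),
                   abundance = feature_matrix(abundance, "abundance"),
                   type_of = type_of,
                   label_of = label_of,
                   latent_truth = latent,
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- length(x$type_of)
  cat(sprintf("synthetic_cohort: %d samples, %d genes, %d type clusters\n",
              n, ncol(x$counts), x$spec$n_types))
  lab <- x$label_of[!is.na(x$label_of)]
  cat(sprintf("  labeled: %d (%.1f%%), responded/progressive = %d/%d\n",
              length(lab), 100 * length(lab) / n,
              sum(lab == 0L), sum(lab == 1L)))
  invisible(x)
}

# clinical vocabularies (as exported by the two portals)
.xena_responded <- c("Complete response", "Partial response")
.xena_progressive <- c("Radiographic progressive disease",
                       "Clinical progressive disease", "Stable disease")
.other_therapies <- c("Hormone Therapy", "Immunotherapy",
                      "Targeted Molecular therapy")

#' Emit a clinical annotation table for a synthetic cohort
#'
#' Writes the cohort's response labels in the column schema and value
#' vocabulary of one of the two real-data sources, so that the labeling
#' module can be tested end to end: [assign_response_labels()] on the
#' emitted table recovers `cohort$label_of` exactly. Unlabeled samples get
#' an empty response field, or a non-chemotherapy therapy annotation (which
#' the labeling rules must ignore).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dialect `"xena"` (columns `submitter_id.samples`, `therapy_type`,
#'   `measure_of_response`) or `"cbioportal"` (columns `Sample_ID`,
#'   `Disease.Free.Status`, `Pharmaceutical.Therapy.Indicator`).
#' @param seed RNG seed for the arbitrary choices (which synonym of a
#'   response category a sample gets, letter case, which non-chemo therapy).
#' @return A `data.frame` in the requested dialect.
#' @export
generate_clinical_table <- function(cohort, dialect = c("xena", "cbioportal"),
                                    seed = 0L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dialect <- match.arg(dialect)
  y <- cohort$label_of
  n <- length(y)
  with_local_seed(seed, {
    if (dialect == "xena") {
      therapy <- rep("Chemotherapy", n)
      response <- character(n)
      for (i in seq_len(n)) {
        if (is.na(y[i])) {
          if (stats::runif(1) < 0.5) {
            response[i] <- ""  # chemo given but response never recorded
          } else {             # treated with something other than chemo
            therapy[i] <- sample(.other_therapies, 1L)
            response[i] <- sample(c(.xena_responded, .xena_progressive), 1L)
          }
        } else {
          vocab <- if (y[i] == 0L) .xena_responded else .xena_progressive
          v <- sample(vocab, 1L)
          if (stats::runif(1) < 0.3) v <- tolower(v)  # raw exports vary in case
          response[i] <- v
        }
      }
      out <- data.frame(`submitter_id.samples` = names(y),
                        therapy_type = therapy,
                        measure_of_response = response,
                        check.names = FALSE)
    } else {
      indicator <- rep("Yes", n)
      status <- character(n)
      for (i in seq_len(n)) {
        if (is.na(y[i])) {
          if (stats::runif(1) < 0.5) {
            status[i] <- ""
          } else {
            indicator[i] <- "No"
            status[i] <- sample(c("DiseaseFree", "Recurred/Progressed"), 1L)
          }
        } else {
          status[i] <- if (y[i] == 0L) {
            sample(c("DiseaseFree", "Disease Free"), 1L)
          } else "Recurred/Progressed"
        }
      }
      out <- data.frame(Sample_ID = names(y),
                        Disease.Free.Status = status,
                        Pharmaceutical.Therapy.Indicator = indicator,
                        check.names = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}
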