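#' Read and write expression matrices as (optionally gzipped) TSV
#'
#' The on-disk dialect used throughout the package: genes as rows, first
#' column the gene id (header `gene_id`), remaining columns one per sample
#' with sample ids in the header. In memory the package works samples x
#' features, so these functions transpose on the way in and out.
#'
#' @param x a [feature_matrix()] (samples x features).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns a [feature_matrix()].
#' @export
write_expression_tsv <- function(x, path) {
  if (!is_feature_matrix(x)) stop("'x' must be a feature_matrix")
  df <- data.frame(gene_id = colnames(x), t(fm_values(x)), check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param state processing-state tag to attach on read.
#' @export
read_expression_tsv <- function(path, state = "counts") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  df <- utils::read.table(con, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene id column plus samples")
  genes <- as.character(df[[1L]])
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(m) <- genes
  feature_matrix(m, state = state)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the counts and abundance matrices as gzipped TSV, clinical tables in
#' both supported dialects, the true labels/types, and a JSON sidecar holding
#' the generating specification (including the seed) for provenance.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(cohort$counts, file.path(dir, "counts.tsv.gz"))
  write_expression_tsv(cohort$abundance, file.path(dir, "abundance.tsv.gz"))
  for (dialect in c("xena", "cbioportal")) {
    tab <- generate_clinical_table(cohort, dialect = dialect)
    utils::write.table(tab, file.path(dir, paste0("clinical_", dialect, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- data.frame(sample_id = names(cohort$type_of),
                      type = unname(cohort$type_of),
                      label = unname(cohort$label_of))
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cohort$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Save or load a fitted encoder with a JSON architecture sidecar
#'
#' The checkpoint is an RDS file holding the full model object, accompanied
#' by a human-readable `<path>.json` sidecar describing the architecture,
#' loss, seed and training length, so runs can be audited without loading R.
#'
#' @param model a fitted [vae()] or [autoencoder()].
#' @param path checkpoint path (conventionally `.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "vae")) stop("'model' must be a fitted vae/autoencoder")
  saveRDS(model, path)
  side <- c(model$architecture[c("name", "input_dim", "latent_dim",
                                 "n_layers", "hidden", "loss", "mc_samples")],
            list(class = class(model)[1L], seed = model$seed,
                 kl_weight = model$kl_weight,
                 epochs_trained = nrow(model$training_log),
                 final_objective = utils::tail(model$training_log$objective,
                                               1)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) NULL)
  if (!inherits(model, "vae")) stop("'", path, "' is not a saved model")
  model
}
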