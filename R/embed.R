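# Two-dimensional embedding diagnostics (t-SNE and UMAP), used to check
# that an encoding preserves cancer-type cluster structure. The embeddings
# are computed by the reference implementations -- scikit-learn's TSNE and
# umap-learn -- through a bundled Python helper script, with the published
# settings as defaults (t-SNE: PCA initialization, perplexity 20, learning
# rate 300, 400 iterations; UMAP: 50 neighbors, min_dist 0.3, euclidean).

find_python <- function() {
  for (cand in c(Sys.getenv("TUMORVAE_PYTHON", ""), "python", "python3")) {
    if (nzchar(cand) && nzchar(Sys.which(cand))) return(Sys.which(cand))
  }
  stop("no 'python' interpreter found on PATH (needed for embed_2d)")
}

#' Embed samples into two dimensions with t-SNE or UMAP
#'
#' @param X samples x features matrix (or [feature_matrix()]).
#' @param method `"tsne"` or `"umap"`.
#' @param params named list overriding the published defaults
#'   (`perplexity`, `learning_rate`, `max_iter` for t-SNE;
#'   `n_neighbors`, `min_dist`, `metric` for UMAP).
#' @param seed integer seed; identical seeds give identical coordinates.
#' @return Samples x 2 numeric matrix (columns `dim1`, `dim2`).
#' @export
embed_2d <- function(X, method = c("tsne", "umap"), params = list(),
                     seed = 1L) {
  method <- match.arg(method)
  xm <- if (is_feature_matrix(X)) fm_values(X) else as.matrix(X)
  n <- nrow(xm)
  defaults <- if (method == "tsne")
    list(perplexity = 20, learning_rate = 300, max_iter = 400)
  else
    list(n_neighbors = 50, min_dist = 0.3, metric = "euclidean")
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) stop("unknown parameter(s) for ", method, ": ",
                        paste(bad, collapse = ", "))
  p <- utils::modifyList(defaults, params)
  if (method == "tsne" && n < 3 * p$perplexity)
    stop("t-SNE with perplexity ", p$perplexity, " needs at least ",
         3 * p$perplexity, " samples; got ", n)
  if (method == "umap" && n <= p$n_neighbors)
    stop("UMAP with n_neighbors ", p$n_neighbors, " needs more than ",
         p$n_neighbors, " samples; got ", n)
  script <- system.file("python", "embed2d.py", package = "tumorvae",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(xm, fin, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  args <- c(script, "--input", fin, "--output", fout,
            "--method", method, "--seed", as.integer(seed))
  for (nm in names(p)) args <- c(args, paste0("--", nm), as.character(p[[nm]]))
  res <- system2(find_python(), args, stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("embed2d.py failed:\n", paste(res, collapse = "\n"))
  out <- as.matrix(utils::read.table(fout, sep = "\t", header = FALSE))
  dimnames(out) <- list(rownames(xm), c("dim1", "dim2"))
  out
}
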