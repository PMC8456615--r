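#' Samples-by-features expression matrix with a processing-state tag
#'
#' The pipeline's working container: a numeric matrix with samples as rows
#' and features (genes or latent dimensions) as columns, plus a `state` tag
#' recording where in the preprocessing chain the values sit. Downstream
#' stages check the tag so that, e.g., a VAE is never fit on unscaled data.
#'
#' @param values numeric matrix, samples x features; must have unique,
#'   non-empty row and column names (sample ids / feature ids).
#' @param state one of `"counts"`, `"log_norm"`, `"minmax"`, `"abundance"`.
#' @return A `feature_matrix` object (a matrix with attributes).
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' fm <- feature_matrix(m, "counts")
#' fm_state(fm)
#' @export
feature_matrix <- function(values,
                           state = c("counts", "log_norm", "minmax", "abundance")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x features)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (sample) and column (feature) names")
  if (anyDuplicated(colnames(values)))
    stop("feature ids must be unique")
  if (anyDuplicated(rownames(values)))
    stop("sample ids must be unique")
  if (anyNA(values))
    stop("feature_matrix must not contain missing values")
  if (state == "counts" && any(values < 0))
    stop("counts must be nonnegative")
  if (state == "minmax" && (any(values < 0) || any(values > 1)))
    stop("state 'minmax' requires all values in [0, 1]")
  structure(values, state = state, class = c("feature_matrix", class(values)))
}

#' @rdname feature_matrix
#' @param x a `feature_matrix`.
#' @export
fm_state <- function(x) attr(x, "state")

#' @rdname feature_matrix
#' @export
is_feature_matrix <- function(x) inherits(x, "feature_matrix")

fm_values <- function(x) {
  y <- unclass(x)
  attr(y, "state") <- NULL
  y
}

assert_state <- function(x, state) {
  if (!is_feature_matrix(x))
    stop("expected a feature_matrix, got ", class(x)[1L])
  if (!identical(fm_state(x), state))
    stop("expected feature_matrix in state '", state, "', got '", fm_state(x), "'")
  invisible(x)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d samples x %d features\n",
              fm_state(x), nrow(x), ncol(x)))
  if (nrow(x) && ncol(x)) {
    show <- x[seq_len(min(4L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE]
    print(round(unclass(show), 4))
    if (ncol(x) > 6L || nrow(x) > 4L) cat("...\n")
  }
  invisible(x)
}
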