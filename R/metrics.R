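# Classification performance metrics and the logit-scale Welch comparison
# used to contrast feature sets across cross-validation replications.

check_binary <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1 with no missing values")
  labels
}

#' Area under the ROC curve
#'
#' The rank statistic: the probability that a randomly chosen positive
#' (`label == 1`) receives a higher score than a randomly chosen negative,
#' counting ties as 1/2. Invariant to monotone transformations of the
#' scores.
#'
#' @param labels binary 0/1 vector (1 = positive class).
#' @param scores numeric scores, higher meaning more likely positive.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6))  # 0.75
#' @export
auroc <- function(labels, scores) {
  labels <- check_binary(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC needs both classes present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration over the stepwise precision-recall points, one
#' point per distinct score threshold (descending). The recall-0 anchor
#' uses the precision at the highest threshold, so that a scoreless
#' (all-tied) classifier obtains exactly the class prevalence, and a
#' perfect ranking obtains 1.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(labels, scores) {
  labels <- check_binary(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  if (sum(labels == 1L) == 0L) stop("AUPRC needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # cut points after the last element of each tied score block
  last_of_block <- which(!duplicated(sc, fromLast = TRUE))
  tp <- cumsum(lab)[last_of_block]
  fp <- cumsum(1 - lab)[last_of_block]
  precision <- tp / (tp + fp)
  recall <- tp / sum(lab)
  recall <- c(0, recall)
  precision <- c(precision[1L], precision)
  sum(diff(recall) * (utils::head(precision, -1) +
                        utils::tail(precision, -1)) / 2)
}

#' Welch comparison of two replication vectors on the logit scale
#'
#' AUROC/AUPRC replication values are logit-transformed (after clamping
#' away from 0 and 1) and compared with a two-tailed unequal-variance
#' (Welch) t-test. Two identical or zero-variance groups return `p = 1`
#' with `degenerate = TRUE` rather than an error.
#'
#' @param group_a,group_b numeric vectors of per-replication metric values
#'   in `[0, 1]` (at least 2 each).
#' @param clamp values are clipped to `[clamp, 1 - clamp]` before the logit
#'   (default 1e-3), avoiding infinities when a replication hits 0 or 1.
#' @return A list: `mean_a`, `mean_b` (on the original scale), `statistic`,
#'   `p_value`, `degenerate`.
#' @examples
#' logit_welch_compare(c(0.7, 0.72, 0.69), c(0.6, 0.61, 0.63))
#' @export
logit_welch_compare <- function(group_a, group_b, clamp = 1e-3) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  lg <- function(v) stats::qlogis(pmin(pmax(v, clamp), 1 - clamp))
  la <- lg(group_a); lb <- lg(group_b)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    return(list(mean_a = mean(group_a), mean_b = mean(group_b),
                statistic = 0, p_value = 1, degenerate = TRUE))
  }
  tt <- tryCatch(stats::t.test(la, lb, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    return(list(mean_a = mean(group_a), mean_b = mean(group_b),
                statistic = 0, p_value = 1, degenerate = TRUE))
  }
  list(mean_a = mean(group_a), mean_b = mean(group_b),
       statistic = unname(tt$statistic), p_value = tt$p.value,
       degenerate = FALSE)
}
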