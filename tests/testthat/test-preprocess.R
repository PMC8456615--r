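counts_fm <- function(m) feature_matrix(m, "counts")

test_that("log total-count normalization matches the hand-worked example", {
  m <- matrix(c(3, 1), 1, 2,
              dimnames = list("s1", c("g1", "g2")))
  out <- log_total_count_normalize(counts_fm(m), target_depth = 4)
  expect_equal(unclass(out)[1, ], c(g1 = 2, g2 = 1))
  expect_identical(fm_state(out), "log_norm")
})

test_that("an all-zero gene stays a row of zeros and scaling is depth-invariant", {
  set.seed(1)
  m <- matrix(rpois(40, 20), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:10)))
  m[, 3] <- 0
  out <- log_total_count_normalize(counts_fm(m))
  expect_true(all(unclass(out)[, 3] == 0))
  # doubling all counts of one sample leaves that sample's output unchanged
  m2 <- m; m2[2, ] <- 2 * m[2, ]
  out2 <- log_total_count_normalize(counts_fm(m2),
                                    target_depth = median(rowSums(m)))
  base <- log_total_count_normalize(counts_fm(m),
                                    target_depth = median(rowSums(m)))
  expect_equal(unclass(out2)[2, ], unclass(base)[2, ])
})

test_that("zero-total samples are reported by id", {
  m <- matrix(c(0, 1, 0, 2), 2, 2,
              dimnames = list(c("bad", "ok"), c("g1", "g2")))
  expect_error(log_total_count_normalize(counts_fm(m)), "bad")
})

test_that("per-gene MAD agrees with a brute-force oracle", {
  expect_equal(mad_per_gene(counts_fm(matrix(5, 4, 1,
    dimnames = list(paste0("s", 1:4), "g1"))))[["g1"]], 0)
  m <- matrix(1:5, 5, 1, dimnames = list(paste0("s", 1:5), "g1"))
  expect_equal(mad_per_gene(counts_fm(m))[["g1"]], 1.4826)
  set.seed(42)
  for (i in 1:100) {
    v <- rnorm(sample(3:30, 1), sd = runif(1, 0.1, 50))
    fm <- feature_matrix(matrix(v, length(v), 1,
      dimnames = list(paste0("s", seq_along(v)), "g1")), "abundance")
    expect_lt(abs(mad_per_gene(fm)[["g1"]] - mad_brute(v)), 1e-12)
  }
})

test_that("MAD is invariant to sample order and needs two samples", {
  set.seed(7)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("g", 1:10)))
  fm <- feature_matrix(m, "abundance")
  perm <- feature_matrix(m[sample(6), ], "abundance")
  expect_equal(mad_per_gene(fm), mad_per_gene(perm))
  one <- feature_matrix(m[1, , drop = FALSE], "abundance")
  expect_error(mad_per_gene(one), "2 samples")
})

test_that("top-variance selection takes the right genes per group and unions", {
  mk <- function(sds, seed) {
    set.seed(seed)
    m <- sapply(sds, function(s) rnorm(20, sd = s))
    dimnames(m) <- list(paste0("s", 1:20), paste0("g", seq_along(sds)))
    feature_matrix(m, "abundance")
  }
  g1 <- mk(c(10, 9, rep(0.1, 8)), 1)   # top-2: g1, g2
  res <- select_top_variance_union(list(a = g1), quantile = 0.2)
  expect_setequal(res$selected_ids, c("g1", "g2"))

  g2 <- mk(c(rep(0.1, 8), 9, 10), 2)   # top-2: g9, g10
  res2 <- select_top_variance_union(list(a = g1, b = g2), quantile = 0.2)
  expect_setequal(res2$selected_ids, c("g1", "g2", "g9", "g10"))
  # deterministic lexicographic order
  expect_identical(res2$selected_ids, sort(res2$selected_ids))
  # identical groups collapse to a single selection
  res3 <- select_top_variance_union(list(a = g1, b = g1), quantile = 0.2)
  expect_setequal(res3$selected_ids, res$selected_ids)
})

test_that("ties at the quantile boundary are kept inclusively", {
  m <- matrix(rep(c(0, 10), each = 4), 4, 2)  # build 3 genes, two tied
  m <- cbind(c(0, 0, 0, 0), c(1, 5, 9, 13), c(2, 6, 10, 14))
  dimnames(m) <- list(paste0("s", 1:4), c("flat", "t1", "t2"))
  fm <- feature_matrix(m, "abundance")
  res <- select_top_variance_union(list(a = fm), quantile = 1 / 3)
  expect_setequal(res$selected_ids, c("t1", "t2"))  # equal MAD: keep both
})

test_that("min-max scaling follows the fit/apply contract", {
  ref <- feature_matrix(matrix(c(2, 4, 6, 3, 3, 3), 3, 2,
    dimnames = list(paste0("s", 1:3), c("a", "b"))), "log_norm")
  mm <- minmax_fit(ref)
  out <- minmax_apply(ref, mm)
  expect_equal(unclass(out)[, "a"], c(s1 = 0, s2 = 0.5, s3 = 1))
  expect_equal(unname(unclass(out)[, "b"]), c(0, 0, 0))  # constant -> 0
  # out-of-range new values clip to [0, 1]
  new <- feature_matrix(matrix(c(8, 1, 3, 3), 2, 2,
    dimnames = list(c("n1", "n2"), c("a", "b"))), "log_norm")
  applied <- minmax_apply(new, mm)
  expect_equal(unname(unclass(applied)[, "a"]), c(1, 0))
  expect_identical(fm_state(applied), "minmax")
  expect_error(minmax_apply(new, list()), "minmax_fit")
})

test_that("scaling with fixed params commutes with sample subsetting", {
  set.seed(3)
  ref <- feature_matrix(matrix(rnorm(50), 10, 5,
    dimnames = list(paste0("s", 1:10), paste0("g", 1:5))), "log_norm")
  mm <- minmax_fit(ref)
  full <- minmax_apply(ref, mm)
  sub <- feature_matrix(unclass(ref)[3:6, ], "log_norm")
  expect_equal(unclass(minmax_apply(sub, mm)), unclass(full)[3:6, ],
               ignore_attr = TRUE)
})

test_that("the full pipeline lands in the unit hypercube", {
  co <- small_cohort()
  prep <- preprocess_cohort(co$counts, co$abundance, group = co$type_of)
  expect_true(all(prep$features >= 0 & prep$features <= 1))
  expect_identical(fm_state(prep$features), "minmax")
  expect_true(all(prep$filter$selected_ids %in% colnames(co$counts)))
})
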