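# ROC AUC, discriminative-mass calling, summaries, overlap.

test_that("AUC handles separation, ties, and empty inputs", {
  expect_equal(roc_auc(c(3, 4), c(1, 2)), 1.0)
  expect_equal(roc_auc(c(1, 2), c(3, 4)), 0.0)
  expect_equal(roc_auc(c(1, 1, 1), c(1, 1, 1)), 0.5)
  expect_error(roc_auc(numeric(0), 1), "nonempty")
  expect_error(roc_auc(1, numeric(0)), "nonempty")
})

test_that("rank-based AUC equals the pairwise oracle and satisfies the complement identity", {
  set.seed(42)
  for (i in 1:100) {
    np <- sample(2:50, 1); nn <- sample(2:50, 1)
    # mix continuous values and ties
    pool <- if (i %% 2) rnorm(np + nn) else sample(0:5, np + nn, replace = TRUE)
    p <- pool[seq_len(np)]; n <- pool[np + seq_len(nn)]
    a <- roc_auc(p, n)
    expect_equal(a, auc_pairwise(p, n), tolerance = 1e-12)
    expect_identical(a + roc_auc(n, p), 1)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:10) {
    p <- rnorm(30, mean = 0.5); n <- rnorm(25)
    ref <- as.numeric(pROC::auc(
      response = c(rep(1, 30), rep(0, 25)), predictor = c(p, n),
      direction = "<", quiet = TRUE))
    expect_equal(roc_auc(p, n), ref, tolerance = 1e-12)
  }
})

test_that("AUC of identical distributions stays near 1/2", {
  set.seed(11)
  a <- roc_auc(rnorm(200), rnorm(200))
  se <- sqrt((200 + 200 + 1) / (12 * 200 * 200))
  expect_lt(abs(a - 0.5), 3 * se)
})

make_table <- function(values, groups, centers = NULL, sample_ids = NULL) {
  n <- nrow(values)
  if (is.null(centers)) centers <- seq_len(ncol(values)) + 700
  pk <- structure(list(
    peaks = data.frame(center = centers, lo = centers - 0.5,
                       hi = centers + 0.5,
                       coefficient = rep(1, ncol(values))),
    sigma = 0.25, mode = "positive", provenance = list()), class = "peak_set")
  structure(list(
    spots = data.frame(sample_id = sample_ids %||% rep(c("s1", "s2"), length.out = n),
                       group = groups, timepoint = "16w", mode = "positive",
                       x = seq_len(n), y = 0L),
    peaks = pk, values = values), class = "feature_table")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("DM calling is bidirectional with at most one direction per peak", {
  set.seed(1)
  n <- 40
  groups <- rep(c("CTRL", "HFHS"), each = n / 2)
  up <- c(rnorm(n / 2, 10, 0.5), rnorm(n / 2, 30, 0.5))    # higher in HFHS
  down <- c(rnorm(n / 2, 30, 0.5), rnorm(n / 2, 10, 0.5))  # higher in CTRL
  null <- rnorm(n, 20, 0.5)
  tab <- make_table(cbind(up, down, null), groups,
                    sample_ids = rep(c("c1", "c2", "h1", "h2"), each = n / 4))
  dms <- detect_dms(tab, rep(TRUE, n), threshold = 0.7)
  expect_equal(nrow(dms), 2)
  expect_equal(dms$direction[dms$peak == 1], "HFHS_vs_CTRL")
  expect_equal(dms$direction[dms$peak == 2], "CTRL_vs_HFHS")
  expect_true(all(dms$auc >= 0.7))
  expect_lte(max(table(dms$peak)), 1)
  # zero-noise null: no calls
  tab0 <- make_table(matrix(5, n, 3), groups)
  expect_equal(nrow(detect_dms(tab0, rep(TRUE, n))), 0)
  # complement identity at the call level: swapping group labels swaps direction
  tab_sw <- tab; tab_sw$spots$group <- rev(groups)
  dms_sw <- detect_dms(tab_sw, rep(TRUE, n), threshold = 0.7)
  expect_equal(dms_sw$direction[dms_sw$peak == 1], "CTRL_vs_HFHS")
  expect_equal(dms_sw$auc[dms_sw$peak == 1], dms$auc[dms$peak == 1])
})

test_that("DM calling is monotone in the threshold", {
  set.seed(2)
  n <- 60
  groups <- rep(c("CTRL", "HFHS"), each = n / 2)
  vals <- sapply(seq(0, 2, length.out = 12), function(d)
    c(rnorm(n / 2), rnorm(n / 2, d)))
  tab <- make_table(vals, groups)
  d07 <- detect_dms(tab, rep(TRUE, n), threshold = 0.7)
  d08 <- detect_dms(tab, rep(TRUE, n), threshold = 0.8)
  expect_true(all(d08$peak %in% d07$peak))
  expect_error(detect_dms(tab, rep(TRUE, n), threshold = 0.5), "0.5")
})

test_that("empty ROI for a sample is an error", {
  tab <- make_table(matrix(rnorm(40), 20), rep(c("CTRL", "HFHS"), each = 10),
                    sample_ids = rep(c("a", "b"), each = 10))
  roi <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_error(detect_dms(tab, roi), "ROI is empty for sample")
})

test_that("DM summary reproduces row totals from per-cell counts", {
  # published per-cell counts for the earliest and latest feeding times
  counts <- data.frame(
    timepoint = c("16w", "16w", "16w", "16w", "3d", "3d"),
    mode = c("negative", "negative", "positive", "positive", "negative", "positive"),
    direction = c("HFHS_vs_CTRL", "CTRL_vs_HFHS", "HFHS_vs_CTRL", "CTRL_vs_HFHS",
                  "CTRL_vs_HFHS", "CTRL_vs_HFHS"),
    count = c(27, 83, 18, 99, 10, 1))
  s <- dm_summary_from_counts(counts)
  expect_equal(s$total_dms[s$timepoint == "16w"], 227)
  expect_equal(s$total_dms[s$timepoint == "3d"], 11)
  expect_equal(s$total_HFHS_vs_CTRL[s$timepoint == "16w"], 45)
  expect_equal(s$total_CTRL_vs_HFHS[s$timepoint == "16w"], 182)
  # totals are sums of their components on every row
  expect_equal(s$total_dms,
               s$negative_HFHS_vs_CTRL + s$negative_CTRL_vs_HFHS +
                 s$positive_HFHS_vs_CTRL + s$positive_CTRL_vs_HFHS)
  # empty input: all-zero frame
  empty <- summarize_dms(data.frame(timepoint = character(),
                                    mode = character(), direction = character()))
  expect_equal(nrow(empty), 0)
})

test_that("cross-time-point overlap matches identical, disjoint, and shifted lists", {
  a <- data.frame(center_mz = c(700.1, 750.2, 800.3), mode = "positive")
  expect_equal(nrow(overlap_dms(a, a, 0.1)), 3)
  b <- data.frame(center_mz = c(900.0, 950.0), mode = "positive")
  expect_equal(nrow(overlap_dms(a, b, 0.1)), 0)
  # within-tolerance shift matches greedily, nearest first, one-to-one
  c_ <- data.frame(center_mz = c(700.15, 750.25, 820.0), mode = "positive")
  m <- overlap_dms(a, c_, 0.1)
  expect_equal(nrow(m), 2)
  expect_true(all(abs(m$delta_mz) <= 0.1))
  expect_false(any(duplicated(m$idx_a)) || any(duplicated(m$idx_b)))
  # different modes never match
  d <- data.frame(center_mz = 700.1, mode = "negative")
  expect_equal(nrow(overlap_dms(a, d, 0.1)), 0)
})

test_that("DM intensity summary returns per-spot means for one direction", {
  n <- 20
  groups <- rep(c("CTRL", "HFHS"), each = n / 2)
  vals <- cbind(rep(c(1, 2), each = n / 2), rep(c(3, 6), each = n / 2),
                rnorm(n, 10))
  tab <- make_table(vals, groups)
  dms <- data.frame(peak = c(1, 2), direction = "HFHS_vs_CTRL")
  s <- dm_intensity_summary(tab, rep(TRUE, n), dms, "HFHS_vs_CTRL")
  expect_equal(nrow(s), n)
  # fold-2 planted effect on both DM peaks: HFHS median = 2x CTRL median
  expect_equal(median(s$mean_intensity[s$group == "HFHS"]),
               2 * median(s$mean_intensity[s$group == "CTRL"]))
  # single-DM summary equals that peak's column
  s1 <- dm_intensity_summary(tab, rep(TRUE, n),
                             data.frame(peak = 1, direction = "HFHS_vs_CTRL"),
                             "HFHS_vs_CTRL")
  expect_equal(s1$mean_intensity, vals[, 1])
  expect_error(dm_intensity_summary(tab, rep(TRUE, n), dms, "CTRL_vs_HFHS"),
               "no discriminative masses in direction")
})
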