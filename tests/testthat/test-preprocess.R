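# Tophat baseline correction, TIC normalization, mass filters, and the fixed
# preprocessing order.

# direct (slow) morphological opening oracle: flat erosion then dilation
opening_oracle <- function(x, w) {
  h <- w %/% 2
  n <- length(x)
  win <- function(i) max(1, i - h):min(n, i + h)
  ero <- vapply(seq_len(n), function(i) min(x[win(i)]), numeric(1))
  vapply(seq_len(n), function(i) max(ero[win(i)]), numeric(1))
}

test_that("Tophat maps constants to zero and matches the direct morphological oracle", {
  expect_equal(tophat_baseline_correct(rep(7.5, 100), 9), rep(0, 100))
  set.seed(3)
  x <- abs(rnorm(200)) + 2
  for (w in c(3, 9, 25)) {
    expect_equal(tophat_baseline_correct(x, w),
                 pmax(x - opening_oracle(x, w), 0), tolerance = 1e-12)
  }
})

test_that("an isolated narrow peak on a flat zero background is preserved", {
  mzch <- seq_len(301)
  peak <- exp(-0.5 * ((mzch - 150) / 3)^2)
  peak[abs(mzch - 150) > 12] <- 0  # finite support, narrower than the element
  corrected <- tophat_baseline_correct(peak, 31)
  expect_lt(max(abs(corrected - peak)), 1e-9)
})

test_that("a peak on a linear ramp is recovered up to slope x half-width", {
  n <- 400
  slope <- 0.01
  ramp <- slope * seq_len(n)
  peak <- 5 * exp(-0.5 * ((seq_len(n) - 200) / 3)^2)
  w <- 41
  corrected <- tophat_baseline_correct(ramp + peak, w)
  # opening of a pure ramp lags by at most slope * (w-1)/2 at interior points
  err <- max(abs(corrected[50:350] - peak[50:350]))
  expect_lte(err, slope * (w - 1) / 2 + 1e-9)
})

test_that("correction output is nonnegative, dominated by input, and near-idempotent", {
  set.seed(4)
  st <- generate_study(small_config(), 1)
  d <- st$datasets[[1]]
  spec <- d$intensities[10, ]
  corr <- tophat_baseline_correct(spec, 15)
  expect_true(all(corr >= 0))
  expect_true(all(corr <= spec + 1e-12))
  twice <- tophat_baseline_correct(corr, 15)
  # second pass removes < 1% of the remaining intensity
  expect_lt(sum(corr) - sum(twice), 0.01 * sum(corr))
})

test_that("tophat width is validated", {
  expect_error(tophat_baseline_correct(rep(1, 10), 4), "odd")
  expect_error(tophat_baseline_correct(rep(1, 10), 1), "odd")
  expect_error(tophat_baseline_correct(rep(1, 10), 11), "exceeds")
})

make_ds <- function(intens, mz = NULL) {
  n <- nrow(intens)
  ion_image_dataset("s", "CTRL", "3d", "positive",
                    data.frame(x = seq_len(n) - 1L, y = 0L),
                    mz %||% (400 + seq_len(ncol(intens))), intens)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TIC normalization equalizes spot sums and preserves within-spot ratios", {
  d <- make_ds(rbind(c(1, 2, 7), c(4, 6, 10)))
  u <- tic_normalize(d, "unit_sum")
  expect_equal(rowSums(u$intensities), c(1, 1))
  expect_equal(u$intensities[1, 2] / u$intensities[1, 1], 2)
  m <- tic_normalize(d, "mean_tic")
  expect_equal(rowSums(m$intensities), c(15, 15))  # mean of 10 and 20
  # a single spot is unchanged under mean_tic
  one <- make_ds(matrix(c(3, 4, 5), 1))
  expect_equal(tic_normalize(one, "mean_tic")$intensities, one$intensities)
})

test_that("post-normalization TIC coefficient of variation is zero", {
  set.seed(5)
  d <- make_ds(matrix(runif(30 * 40, 0.1, 5), 30))
  u <- tic_normalize(d, "unit_sum")
  tics <- rowSums(u$intensities)
  expect_equal(sd(tics) / mean(tics), 0, tolerance = 1e-12)
})

test_that("zero-TIC spots are dropped with a warning, never imputed", {
  d <- make_ds(rbind(c(1, 2, 3), c(0, 0, 0), c(2, 2, 2)))
  expect_warning(u <- tic_normalize(d), "zero-TIC")
  expect_equal(n_spots(u), 2)
  expect_equal(u$coords$x, c(0L, 2L))
  all_zero <- make_ds(matrix(0, 2, 3))
  expect_error(suppressWarnings(tic_normalize(all_zero)), "all spots")
})

test_that("mass filters apply deflection and exclusion windows consistently", {
  mz <- seq(350, 600, by = 1)
  d <- make_ds(matrix(1, 3, length(mz)), mz)
  p <- preprocess_params(tophat_width = 5)
  f <- apply_mass_filters(d, p)
  expect_gte(min(f$mz), 400)
  expect_false(any(f$mz >= 493 & f$mz <= 507))
  expect_equal(ncol(f$intensities), length(f$mz))
  expect_equal(n_spots(f), 3)
  # empty exclusion list and no low channels: identity
  d2 <- make_ds(matrix(1, 2, 50), 700 + seq_len(50))
  p2 <- preprocess_params(tophat_width = 5, exclusion_windows = list())
  f2 <- apply_mass_filters(d2, p2)
  expect_equal(f2$mz, d2$mz)
  expect_equal(f2$intensities, d2$intensities)
  # removing every channel is an error
  d3 <- make_ds(matrix(1, 2, 5), seq(494, 506, length.out = 5))
  expect_error(apply_mass_filters(d3, p), "every channel")
})

test_that("exclusion window removes the planted matrix peak from downstream tables", {
  cfg <- small_config(noise_sigma = 0, tic_sigma = 0, sample_jitter = 0)
  st <- generate_study(cfg, 1)
  expect_true(any(abs(st$manifest$peaks$mz - 500) < 1e-9))  # artifact planted
  d <- preprocess_dataset(st$datasets[[1]], small_params())
  expect_false(any(d$mz >= 493 & d$mz <= 507))
  ms <- mean_spectrum(list(d))
  pk <- omp_detect_peaks(ms, sigma = cfg$sigma_peak)
  expect_false(any(abs(pk$peaks$center - 500) < 7))
})

test_that("parameter validation rejects malformed windows and widths", {
  expect_error(preprocess_params(tophat_width = 10), "odd")
  expect_error(preprocess_params(exclusion_windows = list(c(507, 493))),
               "low < high")
  expect_error(preprocess_params(exclusion_windows = list(c(300, 350))),
               "within")
})

test_that("the pipeline enforces the filter -> baseline -> normalize order", {
  st <- generate_study(small_config(), 1)
  d <- preprocess_dataset(st$datasets[[1]], small_params())
  log <- attr(d, "preprocess_log")
  expect_equal(log$order, c("mass_filters", "tophat", "tic_normalize"))
  expect_equal(rowSums(d$intensities), rep(1, n_spots(d)), tolerance = 1e-9)
  expect_false(any(d$mz >= 493 & d$mz <= 507))
  # order matters: normalizing before filtering yields different TICs
  alt <- tic_normalize(st$datasets[[1]], "unit_sum")
  alt <- apply_mass_filters(alt, small_params())
  expect_false(isTRUE(all.equal(rowSums(alt$intensities),
                                rep(1, n_spots(alt)))))
})
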