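# Mean/skyline spectra, OMP peak detection, feature extraction.

gauss_spec <- function(mz, centers, amps, sigma = 0.25) {
  y <- numeric(length(mz))
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-0.5 * ((mz - centers[i]) / sigma)^2)
  structure(y, mz = mz)
}

test_that("mean spectrum equals the brute-force column mean", {
  mz <- 400 + seq_len(30)
  one <- ion_image_dataset("a", "CTRL", "3d", "positive",
                           data.frame(x = 0L, y = 0L), mz,
                           matrix(runif(30), 1))
  expect_equal(as.numeric(mean_spectrum(one)), as.numeric(one$intensities))
  two <- ion_image_dataset("b", "HFHS", "3d", "positive",
                           data.frame(x = 0:1, y = 0L), mz,
                           rbind(rep(0:2, 10), rep(2:0, 10)))
  expect_equal(as.numeric(mean_spectrum(two)), rep(1, 30))
  set.seed(6)
  stack <- lapply(1:3, function(i)
    ion_image_dataset(paste0("s", i), "CTRL", "3d", "positive",
                      data.frame(x = 0:4, y = i), mz,
                      matrix(runif(150), 5)))
  all_rows <- do.call(rbind, lapply(stack, `[[`, "intensities"))
  expect_equal(as.numeric(mean_spectrum(stack)), colMeans(all_rows))
  # axis mismatch errors
  off <- stack[[1]]; off$mz <- off$mz + 0.5
  expect_error(mean_spectrum(list(stack[[2]], off)), "share")
})

test_that("skyline spectrum is the per-channel maximum and dominates the mean", {
  mz <- 400 + seq_len(20)
  set.seed(7)
  stack <- lapply(1:3, function(i)
    ion_image_dataset(paste0("s", i), "CTRL", "3d", "positive",
                      data.frame(x = 0:3, y = i), mz,
                      matrix(runif(80), 4)))
  all_rows <- do.call(rbind, lapply(stack, `[[`, "intensities"))
  sky <- skyline_spectrum(stack)
  expect_equal(as.numeric(sky), apply(all_rows, 2, max))
  expect_true(all(sky >= mean_spectrum(stack)))
  one <- skyline_spectrum(stack[[1]])
  expect_equal(as.numeric(one), apply(stack[[1]]$intensities, 2, max))
})

test_that("OMP recovers a single noise-free Gaussian within half a channel", {
  mz <- seq(700, 800, by = 0.1)
  y <- gauss_spec(mz, 760.59, 10)
  pk <- omp_detect_peaks(y, sigma = 0.25)
  expect_equal(nrow(pk$peaks), 1)
  expect_lt(abs(pk$peaks$center - 760.59), 0.05)
})

test_that("OMP selects the larger of two separated peaks first", {
  mz <- seq(700, 800, by = 0.1)
  y <- gauss_spec(mz, c(720, 770), c(1, 10))
  pk <- omp_detect_peaks(y, sigma = 0.25, max_peaks = 1)
  expect_equal(nrow(pk$peaks), 1)
  expect_lt(abs(pk$peaks$center - 770), 0.05)
})

test_that("OMP recovers k well-separated peaks exactly, with monotone residuals", {
  set.seed(8)
  mz <- seq(600, 1000, by = 0.1)
  for (k in c(3, 8, 15)) {
    centers <- sort(600 + 20 + (400 - 40) * (seq_len(k) - 0.5) / k +
                      runif(k, -3, 3))
    amps <- runif(k, 2, 20)
    y <- gauss_spec(mz, centers, amps)
    pk <- omp_detect_peaks(y, sigma = 0.25, residual_tol = 0.01)
    expect_equal(nrow(pk$peaks), k)
    expect_true(all(abs(pk$peaks$center - centers) <= 0.1))
    rn <- pk$provenance$residual_norms
    expect_true(all(diff(rn) <= 1e-9))
    # intervals are sorted and pairwise disjoint
    p <- pk$peaks
    expect_true(all(diff(p$center) > 0))
    expect_true(all(p$lo[-1] >= p$hi[-nrow(p)] - 1e-9))
  }
})

test_that("an all-zero spectrum yields an empty peak set", {
  mz <- seq(500, 600, by = 0.1)
  pk <- omp_detect_peaks(structure(numeric(length(mz)), mz = mz), sigma = 0.25)
  expect_equal(nrow(pk$peaks), 0)
})

test_that("feature extraction integrates peaks and applies centroid matching", {
  mz <- seq(700, 720, by = 0.1)
  centers <- c(705, 715)
  pkset <- omp_detect_peaks(gauss_spec(mz, centers, c(5, 5)), sigma = 0.25)
  # spot 1: peak only at 705; spot 2: zero signal; spot 3: peak shifted +0.3
  ints <- rbind(gauss_spec(mz, 705, 4),
                numeric(length(mz)),
                gauss_spec(mz, 705.3, 4))
  d <- ion_image_dataset("s", "CTRL", "3d", "positive",
                         data.frame(x = 0:2, y = 0L), mz, ints)
  ft <- extract_features(d, pkset)
  expect_equal(dim(ft$values), c(3, 2))
  # integrated intensity approximates the analytic Gaussian area / step
  area <- 4 * 0.25 * sqrt(2 * pi) / 0.1
  expect_equal(ft$values[1, 1], area, tolerance = 0.01)
  expect_equal(ft$values[2, ], c(0, 0))
  # shifted peak (< half-width) still accepted, with comparable intensity
  expect_gt(ft$values[3, 1], 0.95 * area)
  expect_equal(ft$values[, 2], c(0, 0, 0))
  # peak interval outside the axis errors
  bad <- pkset; bad$peaks$lo[1] <- 600
  expect_error(extract_features(d, bad), "outside")
})

test_that("feature columns conserve integrated region signal for isolated peaks", {
  res <- small_feature_table(seed = 2,
                             config = small_config(noise_sigma = 0,
                                                   tic_sigma = 0,
                                                   sample_jitter = 0))
  d <- res$prep[[1]]
  ft <- extract_features(d, res$peaks)
  for (k in seq_len(min(5, ncol(ft$values)))) {
    jj <- which(d$mz >= res$peaks$peaks$lo[k] & d$mz <= res$peaks$peaks$hi[k])
    direct <- rowSums(d$intensities[, jj, drop = FALSE])
    # centroid matching may only zero rows, never inflate them
    expect_true(all(ft$values[, k] <= direct + 1e-9))
    expect_gt(sum(ft$values[, k]) / max(sum(direct), 1e-12), 0.99)
  }
})

test_that("average peak intensity summarizes an ROI and scales with planted effects", {
  vals <- matrix(3.5, 4, 5)
  tab <- structure(list(
    spots = data.frame(sample_id = "s", group = "CTRL", timepoint = "3d",
                       mode = "positive", x = 0:3, y = 0L),
    peaks = NULL, values = vals), class = "feature_table")
  expect_equal(average_peak_intensity(tab, rep(TRUE, 4)), 3.5)
  tab$values[1, ] <- c(1, 3, 1, 3, 2)
  expect_equal(average_peak_intensity(tab, c(TRUE, rep(FALSE, 3))), 2)
  expect_error(average_peak_intensity(tab, rep(FALSE, 4)), "no spots")
})
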