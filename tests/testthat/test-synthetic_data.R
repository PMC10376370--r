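# Ground-truth generator: determinism, null configuration, planted effects,
# manifest consistency.

test_that("identical (config, seed) gives bit-identical datasets", {
  cfg <- small_config(grid = c(8L, 8L))
  a <- generate_study(cfg, 7)
  b <- generate_study(cfg, 7)
  expect_identical(a$manifest$peaks, b$manifest$peaks)
  for (k in names(a$datasets))
    expect_identical(a$datasets[[k]]$intensities, b$datasets[[k]]$intensities)
  c_ <- generate_study(cfg, 8)
  expect_false(identical(a$datasets[[1]]$intensities,
                         c_$datasets[[1]]$intensities))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_study(small_config(grid = c(6L, 6L)), 1))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("null configuration: no DRLs, no noise -> groups are identical", {
  cfg <- small_config(noise_sigma = 0, tic_sigma = 0, sample_jitter = 0,
                      baseline_amplitude = 0,
                      n_drl_up = 0L, n_drl_down = 0L,
                      design = study_design(timepoints = "3d",
                                            modes = "positive",
                                            samples_per_group = 1L))
  st <- generate_study(cfg, 1)
  man <- st$manifest
  epi <- man$region == "epithelium"
  ctrl <- st$datasets[["CTRL_3d_s1_positive"]]
  hfhs <- st$datasets[["HFHS_3d_s1_positive"]]
  expect_equal(colMeans(ctrl$intensities[epi, ]),
               colMeans(hfhs$intensities[epi, ]))
})

test_that("a planted fold-3 up-DRL triples the epithelium intensity ratio", {
  cfg <- small_config(noise_sigma = 0, tic_sigma = 0, sample_jitter = 0,
                      baseline_amplitude = 1e-12,
                      n_drl_up = 1L, n_drl_down = 0L, fold_change = 3,
                      design = study_design(timepoints = "3d",
                                            modes = "positive",
                                            samples_per_group = 1L))
  st <- generate_study(cfg, 2)
  man <- st$manifest
  drl <- man$drls
  expect_equal(nrow(drl), 1)
  expect_equal(drl$direction, "up_in_HFHS")
  epi <- man$region == "epithelium"
  ch <- abs(st$datasets[[1]]$mz - drl$mz) < 0.05
  ctrl <- mean(st$datasets[["CTRL_3d_s1_positive"]]$intensities[epi, ch])
  hfhs <- mean(st$datasets[["HFHS_3d_s1_positive"]]$intensities[epi, ch])
  expect_equal(hfhs / ctrl, 3, tolerance = 1e-9)
  # stroma is not scaled
  str_ <- man$region == "stroma"
  ctrl_s <- mean(st$datasets[["CTRL_3d_s1_positive"]]$intensities[str_, ch])
  hfhs_s <- mean(st$datasets[["HFHS_3d_s1_positive"]]$intensities[str_, ch])
  expect_equal(hfhs_s / ctrl_s, 1, tolerance = 1e-9)
})

test_that("declared DRLs with fold change 1 are a config error", {
  expect_error(small_config(fold_change = 1), "!= 1")
  expect_error(small_config(fold_change = -2), "positive")
  # no DRLs requested: fold change unused, no error
  expect_s3_class(small_config(n_drl_up = 0L, n_drl_down = 0L,
                               fold_change = 1),
                  "synthetic_config")
})

test_that("per-spot TIC multipliers match the configured lognormal scale", {
  cfg <- small_config(tic_sigma = 0.15)
  st <- generate_study(cfg, 1)
  for (key in names(st$manifest$draws)[1:2]) {
    tic <- st$manifest$draws[[key]]$tic
    expect_lt(abs(sd(log(tic)) - 0.15) / 0.15, 0.10)
    expect_lt(abs(mean(log(tic))), 3 * 0.15 / sqrt(length(tic)))
  }
})

test_that("manifest invariants hold: DRLs are planted peaks, regions cover the grid", {
  st <- generate_study(small_config(), 4)
  man <- st$manifest
  expect_true(all(man$drls$mz %in% man$peaks$mz))
  expect_true(all(man$region %in% c("epithelium", "stroma", "background")))
  expect_equal(length(man$region), nrow(man$coords))
  expect_equal(length(man$region), n_spots(st$datasets[[1]]))
  expect_true(all(man$drls$fold_change > 0 & man$drls$fold_change != 1))
  # planted direction matches the generated epithelium group-mean difference
  epi <- man$region == "epithelium"
  ctrl <- st$datasets[["CTRL_16w_s1_positive"]]
  hfhs <- st$datasets[["HFHS_16w_s1_positive"]]
  for (i in seq_len(nrow(man$drls))) {
    ch <- abs(ctrl$mz - man$drls$mz[i]) < 0.3
    dlt <- mean(hfhs$intensities[epi, ch]) - mean(ctrl$intensities[epi, ch])
    expect_equal(dlt > 0, man$drls$direction[i] == "up_in_HFHS")
  }
})

test_that("the reference mask is the epithelium ring", {
  st <- generate_study(small_config(), 5)
  m <- reference_mask(st$manifest)
  expect_s3_class(m, "roi_mask")
  expect_equal(m$source, "reference")
  expect_equal(sum(m$mask), sum(st$manifest$region == "epithelium"))
  expect_identical(m$mask, st$manifest$region == "epithelium")
  # a manifest without epithelium errors
  broken <- st$manifest
  broken$region[broken$region == "epithelium"] <- "stroma"
  expect_error(reference_mask(broken), "no epithelium")
})

test_that("peak placement respects the m/z windows and separation", {
  st <- generate_study(small_config(), 6)
  pk <- st$manifest$peaks
  tissue <- pk$profile %in% c("shared", "epithelium", "stroma")
  expect_gt(mean(pk$mz[tissue] >= 700 & pk$mz[tissue] <= 900), 0.5)
  sep <- min(diff(sort(pk$mz)))
  expect_gte(sep, 6 * st$manifest$sigma_peak)
  # lipid-derived peaks carry a class and adduct; unassigned carry neither
  derived <- !is.na(pk$lipid_class)
  expect_true(all(!is.na(pk$adduct[derived])))
  expect_true(any(derived) && any(!derived & tissue))
})
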