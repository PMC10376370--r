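# Synthetic two-group ion-image study generator with planted ground truth.
#
# Emulates the structure of a diet study on oviduct sections: a spot grid with
# an epithelium ring around the lumen, surrounding stroma, and off-tissue
# background; Gaussian peaks in m/z 400-2000 concentrated near 700-900; two
# diet groups x up to six time points x three sections per group; planted
# differentially regulated lipids (DRLs) in both directions restricted to the
# epithelium; a smooth positive baseline; per-spot TIC variation; a per-section
# intensity jitter; additive truncated-Gaussian noise; and a matrix-cluster
# artifact near m/z 500 for the exclusion-window step to remove.
#
# Every planted quantity is recorded in a ground-truth manifest so downstream
# stages can be scored without external data.

#' Study design
#'
#' The factorial layout of a study: which time points, groups, sections per
#' group, and ionization modes to generate.
#'
#' @param timepoints Subset of `"3d"`, `"1w"`, `"4w"`, `"8w"`, `"12w"`,
#'   `"16w"`.
#' @param groups Subset of `"CTRL"`, `"HFHS"` (both needed for any group
#'   comparison).
#' @param samples_per_group Sections per group per time point (default 3,
#'   three animals per treatment per time point).
#' @param modes Ionization modes to simulate.
#' @return A list of class `study_design`.
#' @export
study_design <- function(timepoints = TIMEPOINT_LEVELS,
                         groups = GROUP_LEVELS,
                         samples_per_group = 3L,
                         modes = MODE_LEVELS) {
  timepoints <- match.arg(timepoints, TIMEPOINT_LEVELS, several.ok = TRUE)
  groups <- match.arg(groups, GROUP_LEVELS, several.ok = TRUE)
  modes <- match.arg(modes, MODE_LEVELS, several.ok = TRUE)
  if (samples_per_group < 1L) stop_ovimsi("samples_per_group must be >= 1")
  structure(list(timepoints = timepoints, groups = groups,
                 samples_per_group = as.integer(samples_per_group),
                 modes = modes),
            class = "study_design")
}

#' Synthetic study configuration
#'
#' All knobs of the generator. Defaults emulate the acquisition described for
#' the real study where one is stated (m/z 400-2000 axis, 3 sections per
#' group, both ionization modes, peaks concentrated near m/z 700-900 with a
#' minor component near 1400-1600, a matrix-cluster artifact near m/z 500);
#' the rest are fixed realistic choices documented in the methods vignette.
#'
#' @param grid `c(nx, ny)` spot grid size; the tissue is a ring (epithelium)
#'   around a lumen, embedded in stroma, with off-tissue background outside.
#' @param mz_range m/z axis limits in Thomson.
#' @param mz_step Channel spacing in Thomson (default 0.1).
#' @param sigma_peak Gaussian peak width sigma, Thomson.
#' @param n_shared,n_epithelium,n_stroma Numbers of tissue peaks shared by
#'   both tissue regions, preferentially epithelial, and preferentially
#'   stromal.
#' @param n_background Off-tissue (matrix-like) peaks besides the m/z-500
#'   artifact.
#' @param mz_windows,window_weights Peak-placement mixture: windows in
#'   Thomson and their probabilities (remaining mass is spread over the rest
#'   of the axis).
#' @param frac_unassigned Fraction of tissue peaks drawn at random m/z rather
#'   than from the packaged lipid ion masses (exercises the unannotated
#'   path).
#' @param n_drl_up,n_drl_down Planted DRLs raised / lowered in the HFHS
#'   epithelium.
#' @param fold_change Epithelial fold change of the planted DRLs (applied as
#'   `x` for up, `1/x` for down); must be positive and not 1 when DRLs are
#'   requested.
#' @param amp_base Base peak amplitude (arbitrary intensity units).
#' @param baseline_amplitude Baseline amplitude; default 20% of `amp_base`.
#' @param baseline_smooth Baseline smoothness length in channels (knot
#'   spacing of the random positive spline).
#' @param tic_sigma Log-sd of the per-spot lognormal TIC multiplier.
#' @param sample_jitter Log-sd of the per-section lognormal intensity scalar
#'   (section-to-section matrix-deposition variation; removed by TIC
#'   normalization).
#' @param noise_sigma SD of the additive Gaussian channel noise (spectra
#'   are clipped at zero). The default, 5% of the base peak amplitude per
#'   channel, keeps the noise floor well below the baseline so that
#'   zero-clipping is rare and the truncated-additive model behaves like
#'   the shot-to-shot variability of well-accumulated TOF pixel spectra
#'   (hundreds of laser shots summed per raster position).
#' @param matrix_mz Center of the planted matrix-cluster artifact (skipped if
#'   outside `mz_range`).
#' @param design A [study_design()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid = c(18L, 18L),
                             mz_range = c(400, 2000),
                             mz_step = 0.1,
                             sigma_peak = 0.25,
                             n_shared = 30L, n_epithelium = 10L,
                             n_stroma = 10L, n_background = 2L,
                             mz_windows = list(c(700, 900), c(1400, 1600)),
                             window_weights = c(0.8, 0.1),
                             frac_unassigned = 0.3,
                             n_drl_up = 4L, n_drl_down = 4L,
                             fold_change = 2.5,
                             amp_base = 100,
                             baseline_amplitude = NULL,
                             baseline_smooth = 400L,
                             tic_sigma = 0.15,
                             sample_jitter = 0.05,
                             noise_sigma = 5,
                             matrix_mz = 500,
                             design = study_design()) {
  stopifnot(length(grid) == 2, grid >= 4, mz_step > 0, sigma_peak > 0,
            mz_range[1] < mz_range[2], noise_sigma >= 0, tic_sigma >= 0,
            sample_jitter >= 0, amp_base > 0, baseline_smooth > 0)
  if (sum(window_weights) > 1 + 1e-12)
    stop_ovimsi("window_weights must sum to at most 1")
  if ((n_drl_up + n_drl_down) > 0 && (fold_change <= 0 || fold_change == 1))
    stop_ovimsi("fold_change for planted DRLs must be positive and != 1")
  if ((n_drl_up + n_drl_down) > n_shared + n_epithelium)
    stop_ovimsi("more DRLs requested than epithelium-expressed peaks")
  structure(list(
    grid = as.integer(grid), mz_range = mz_range, mz_step = mz_step,
    sigma_peak = sigma_peak, n_shared = as.integer(n_shared),
    n_epithelium = as.integer(n_epithelium), n_stroma = as.integer(n_stroma),
    n_background = as.integer(n_background),
    mz_windows = mz_windows, window_weights = window_weights,
    frac_unassigned = frac_unassigned,
    n_drl_up = as.integer(n_drl_up), n_drl_down = as.integer(n_drl_down),
    fold_change = fold_change, amp_base = amp_base,
    baseline_amplitude = baseline_amplitude %||% (0.2 * amp_base),
    baseline_smooth = as.integer(baseline_smooth),
    tic_sigma = tic_sigma, sample_jitter = sample_jitter,
    noise_sigma = noise_sigma, matrix_mz = matrix_mz, design = design),
    class = "synthetic_config")
}

# ring geometry: lumen (background), epithelium ring, stroma, off-tissue
region_layout <- function(grid) {
  nx <- grid[1]; ny <- grid[2]
  coords <- expand.grid(x = seq_len(nx) - 1L, y = seq_len(ny) - 1L)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  r <- sqrt((coords$x - cx)^2 + (coords$y - cy)^2)
  rmax <- min(nx, ny)
  region <- rep("background", nrow(coords))
  region[r < 0.25 * rmax & r >= 0.14 * rmax] <- "epithelium"
  region[r < 0.47 * rmax & r >= 0.25 * rmax] <- "stroma"
  list(coords = coords, region = region)
}

# draw a peak m/z from the placement mixture, respecting a minimal separation
draw_peak_mz <- function(cfg, ions_mz, placed, lipid_derived) {
  lo <- cfg$mz_range[1] + 10; hi <- cfg$mz_range[2] - 10
  min_sep <- 6 * cfg$sigma_peak
  wins <- cfg$mz_windows
  pw <- cfg$window_weights
  rest_w <- max(0, 1 - sum(pw))
  for (attempt in 1:500) {
    u <- runif(1)
    cum <- cumsum(c(pw, rest_w))
    k <- which(u <= cum)[1]
    if (k <= length(wins)) {
      wlo <- max(lo, wins[[k]][1]); whi <- min(hi, wins[[k]][2])
    } else {
      wlo <- lo; whi <- hi
    }
    if (wlo >= whi) next
    cand <- if (lipid_derived) {
      pool <- which(ions_mz > wlo & ions_mz < whi)
      if (!length(pool)) next
      pool[sample.int(length(pool), 1L)]
    } else NA_integer_
    mz <- if (is.na(cand)) runif(1, wlo, whi) else ions_mz[cand]
    if (!length(placed) || min(abs(placed - mz)) >= min_sep)
      return(list(mz = mz, ion = cand))
  }
  stop_ovimsi("could not place a peak with the requested separation; ",
              "reduce peak counts or widen the m/z windows")
}

# region affinity weights (epithelium, stroma, background) per profile class
REGION_WEIGHTS <- list(
  shared     = c(1,    1,    0.05),
  epithelium = c(1,    0.25, 0.02),
  stroma     = c(0.25, 1,    0.02),
  background = c(0.15, 0.15, 1),
  matrix     = c(0.8,  0.8,  1))

#' Generate a synthetic ion-image study
#'
#' Builds one `ion_image_dataset` per (group, time point, sample, mode) of
#' the configured design and a ground-truth manifest recording the region
#' layout, every planted peak with its region affinities, the planted DRLs
#' with direction and fold change, and the per-section random draws. The
#' spot spectrum model is
#' `TIC_multiplier * section_jitter * (sum of Gaussian peaks + baseline) + noise`,
#' clipped at zero; planted DRL amplitudes in the epithelium are scaled by
#' the fold change for the HFHS group only. Deterministic given
#' `(config, seed)`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed.
#' @return List with `datasets` (named list of `ion_image_dataset`) and
#'   `manifest` (class `msi_manifest`).
#' @export
generate_study <- function(config = synthetic_config(), seed = 1L) {
  if (!inherits(config, "synthetic_config"))
    stop_ovimsi("config must be a synthetic_config")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  lay <- region_layout(config$grid)
  ns <- nrow(lay$coords)
  mz <- seq(config$mz_range[1], config$mz_range[2], by = config$mz_step)
  nc <- length(mz)
  region_idx <- match(lay$region, c("epithelium", "stroma", "background"))

  db <- build_lipid_db()
  peaks <- list()
  for (mode in config$design$modes) {
    ions <- lipid_ion_mz(db, mode)
    placed <- numeric(0)
    add_peak <- function(profile, lipid_derived) {
      p <- draw_peak_mz(config, ions$theoretical_mz, placed, lipid_derived)
      placed <<- c(placed, p$mz)
      sp <- if (!is.na(p$ion)) ions[p$ion, ] else NULL
      data.frame(
        mode = mode, mz = p$mz, profile = profile,
        amplitude = config$amp_base * exp(rnorm(1, 0, 0.4)),
        lipid_class = if (is.null(sp)) NA_character_ else sp$lipid_class,
        carbons = if (is.null(sp)) NA_integer_ else sp$carbons,
        double_bonds = if (is.null(sp)) NA_integer_ else sp$double_bonds,
        adduct = if (is.null(sp)) NA_character_ else sp$adduct)
    }
    mode_peaks <- list()
    counts <- c(shared = config$n_shared, epithelium = config$n_epithelium,
                stroma = config$n_stroma, background = config$n_background)
    for (profile in names(counts)) for (i in seq_len(counts[[profile]])) {
      lipid_derived <- profile != "background" &&
        runif(1) >= config$frac_unassigned
      mode_peaks[[length(mode_peaks) + 1L]] <- add_peak(profile, lipid_derived)
    }
    # matrix-cluster artifact, removed downstream by the exclusion window
    if (config$matrix_mz > config$mz_range[1] &&
        config$matrix_mz < config$mz_range[2]) {
      mode_peaks[[length(mode_peaks) + 1L]] <- data.frame(
        mode = mode, mz = config$matrix_mz, profile = "matrix",
        amplitude = 2 * config$amp_base,
        lipid_class = NA_character_, carbons = NA_integer_,
        double_bonds = NA_integer_, adduct = NA_character_)
    }
    pk <- do.call(rbind, mode_peaks)
    # plant DRLs among lipid-derived peaks fully expressed in the epithelium
    pk$is_drl <- FALSE
    pk$direction <- NA_character_
    pk$fold_change <- NA_real_
    n_drl <- config$n_drl_up + config$n_drl_down
    if (n_drl > 0) {
      eligible <- which(pk$profile %in% c("shared", "epithelium") &
                          !is.na(pk$lipid_class))
      if (length(eligible) < n_drl)
        stop_ovimsi("not enough lipid-derived epithelial peaks to plant DRLs; ",
                    "lower frac_unassigned or the DRL counts")
      chosen <- sample(eligible, n_drl)
      pk$is_drl[chosen] <- TRUE
      up <- chosen[seq_len(config$n_drl_up)]
      pk$direction[chosen] <- "down_in_HFHS"
      pk$direction[up] <- "up_in_HFHS"
      pk$fold_change[chosen] <- config$fold_change
    }
    peaks[[mode]] <- pk
  }
  peaks <- do.call(rbind, peaks)
  rownames(peaks) <- NULL

  # region x group peak profiles per mode (epithelium differs between groups
  # through the DRL fold changes; stroma and background are diet-invariant)
  gauss_add <- function(vec, center, amp, sigma) {
    h <- ceiling(5 * sigma / config$mz_step)
    j0 <- which.min(abs(mz - center))
    jj <- max(1, j0 - h):min(nc, j0 + h)
    vec[jj] <- vec[jj] + amp * exp(-0.5 * ((mz[jj] - center) / sigma)^2)
    vec
  }
  profiles <- list()
  for (mode in config$design$modes) {
    pk <- peaks[peaks$mode == mode, ]
    prof <- list(CTRL = matrix(0, 3, nc), HFHS = matrix(0, 3, nc))
    for (i in seq_len(nrow(pk))) {
      w <- REGION_WEIGHTS[[pk$profile[i]]]
      for (g in c("CTRL", "HFHS")) {
        fold <- 1
        if (isTRUE(pk$is_drl[i]) && g == "HFHS")
          fold <- if (pk$direction[i] == "up_in_HFHS") pk$fold_change[i]
                  else 1 / pk$fold_change[i]
        # fold applies in the epithelium only (row 1)
        prof[[g]][1, ] <- gauss_add(prof[[g]][1, ], pk$mz[i],
                                    pk$amplitude[i] * w[1] * fold,
                                    config$sigma_peak)
        if (g == "CTRL") {
          prof[[g]][2, ] <- gauss_add(prof[[g]][2, ], pk$mz[i],
                                      pk$amplitude[i] * w[2], config$sigma_peak)
          prof[[g]][3, ] <- gauss_add(prof[[g]][3, ], pk$mz[i],
                                      pk$amplitude[i] * w[3], config$sigma_peak)
        }
      }
    }
    prof$HFHS[2, ] <- prof$CTRL[2, ]
    prof$HFHS[3, ] <- prof$CTRL[3, ]
    profiles[[mode]] <- prof
  }

  random_baseline <- function() {
    n_knots <- max(4L, ceiling(nc / config$baseline_smooth) + 1L)
    kx <- seq(1, nc, length.out = n_knots)
    ky <- config$baseline_amplitude * runif(n_knots, 0.3, 1)
    pmax(0, spline(kx, ky, xout = seq_len(nc))$y)
  }

  datasets <- list()
  draws <- list()
  des <- config$design
  for (mode in des$modes) for (tp in des$timepoints) for (g in des$groups) {
    for (k in seq_len(des$samples_per_group)) {
      sample_id <- sprintf("%s_%s_s%d", g, tp, k)
      jitter <- exp(rnorm(1, 0, config$sample_jitter))
      tic <- exp(rnorm(ns, 0, config$tic_sigma))
      base <- random_baseline()
      intens <- profiles[[mode]][[g]][region_idx, , drop = FALSE]
      intens <- intens + rep(base, each = ns)
      intens <- intens * (tic * jitter)
      if (config$noise_sigma > 0)
        intens <- intens + rnorm(ns * nc, 0, config$noise_sigma)
      intens[intens < 0] <- 0
      ds <- ion_image_dataset(sample_id, g, tp, mode, lay$coords, mz, intens)
      key <- paste(sample_id, mode, sep = "_")
      datasets[[key]] <- ds
      draws[[key]] <- list(jitter = jitter, tic = tic)
    }
  }

  drls <- peaks[peaks$is_drl, , drop = FALSE]
  rownames(drls) <- NULL
  manifest <- structure(list(
    seed = seed, config = config, coords = lay$coords, region = lay$region,
    peaks = peaks, drls = drls,
    baseline = list(amplitude = config$baseline_amplitude,
                    smooth_channels = config$baseline_smooth),
    tic_sigma = config$tic_sigma, noise_sigma = config$noise_sigma,
    sample_jitter = config$sample_jitter, sigma_peak = config$sigma_peak,
    draws = draws), class = "msi_manifest")
  list(datasets = datasets, manifest = manifest)
}

#' @export
print.msi_manifest <- function(x, ...) {
  cat(sprintf(
    "msi_manifest (seed %d): %d spots (%d epithelium), %d planted peaks, %d DRLs\n",
    x$seed, length(x$region), sum(x$region == "epithelium"),
    nrow(x$peaks), nrow(x$drls)))
  invisible(x)
}

#' Reference epithelium mask from the ground truth
#'
#' Stand-in for H&E co-registration: the boolean mask that is true exactly on
#' the epithelium-labeled spots of the generated layout.
#'
#' @param manifest An `msi_manifest` from [generate_study()].
#' @return A [roi_mask()] with `source = "reference"`.
#' @export
reference_mask <- function(manifest) {
  sel <- manifest$region == "epithelium"
  if (!any(sel)) stop_ovimsi("manifest has no epithelium spots")
  roi_mask(manifest$coords, sel, source = "reference")
}
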