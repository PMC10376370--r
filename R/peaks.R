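# Peak detection on the mean spectrum by orthogonal matching pursuit (OMP)
# over a dictionary of unit-norm Gaussian atoms, centroid alignment of the
# detected centers, per-spot feature extraction over the peak intervals, and
# the overview statistics (skyline spectra, average peak intensity).

#' Mean spectrum over datasets
#'
#' Unweighted elementwise mean over all spots of all supplied datasets
#' (which must share one m/z axis).
#'
#' @param datasets A single `ion_image_dataset` or a list of them.
#' @return Numeric vector of length `n_channels`; the shared axis is
#'   attached as attribute `"mz"`.
#' @export
mean_spectrum <- function(datasets) {
  datasets <- as_dataset_list(datasets)
  mz <- shared_axis(datasets)
  total <- Reduce(`+`, lapply(datasets, function(d) colSums(d$intensities)))
  n <- sum(vapply(datasets, n_spots, integer(1)))
  structure(total / n, mz = mz)
}

#' Skyline projection spectrum
#'
#' Per-channel maximum over all spots of all supplied datasets — the
#' overview projection used to display every detected ion signal of a group
#' at once. It dominates the mean spectrum elementwise.
#'
#' @inheritParams mean_spectrum
#' @return Numeric vector of length `n_channels` with attribute `"mz"`.
#' @export
skyline_spectrum <- function(datasets) {
  datasets <- as_dataset_list(datasets)
  mz <- shared_axis(datasets)
  sky <- Reduce(pmax, lapply(datasets, function(d)
    apply(d$intensities, 2, max)))
  structure(sky, mz = mz)
}

as_dataset_list <- function(datasets) {
  if (inherits(datasets, "ion_image_dataset")) list(datasets) else datasets
}

shared_axis <- function(datasets) {
  mz <- datasets[[1]]$mz
  for (d in datasets[-1])
    if (length(d$mz) != length(mz) || any(d$mz != mz))
      stop_ovimsi("datasets do not share one m/z axis")
  mz
}

#' Detect peaks by orthogonal matching pursuit
#'
#' Greedy sparse approximation of the mean spectrum over a dictionary of
#' unit-norm Gaussian atoms (width `sigma`) centered at every channel:
#' each iteration selects the atom with the largest positive inner product
#' with the residual, refits all selected coefficients by least squares
#' (incremental Cholesky on the analytic Gram matrix), and updates the
#' residual. Iteration stops when the relative residual norm drops to
#' `residual_tol`, `max_peaks` atoms are selected, or the best remaining
#' atom correlation falls below `snr_min` times the robust noise level of
#' the spectrum (the median absolute deviation of the atom correlations —
#' the standard signal-to-noise gate of spectral peak pickers, inactive on
#' noise-free spectra); atoms whose refit coefficient is not positive are
#' discarded.
#'
#' Detected centers are then aligned to the mean spectrum by centroid
#' matching: each reported center is the intensity-weighted centroid of the
#' mean spectrum within the peak interval, giving sub-channel accuracy.
#' Peak intervals are `center +/- 3 sigma`, truncated at the midpoint
#' between adjacent centers so they never overlap.
#'
#' @param mean_spec Numeric mean spectrum (e.g., from [mean_spectrum()]).
#' @param mz_axis m/z axis matching `mean_spec`; taken from the `"mz"`
#'   attribute when omitted.
#' @param sigma Gaussian atom width (Thomson).
#' @param max_peaks Maximum number of atoms to select.
#' @param residual_tol Stopping threshold on `||residual|| / ||mean_spec||`.
#' @param snr_min Minimum atom correlation in units of the spectrum's robust
#'   noise level (default 3); set to 0 to disable the gate.
#' @param mode Ionization mode recorded in the result.
#' @return A `peak_set`: data frame `peaks` (center, lo, hi, coefficient),
#'   `sigma`, `mode`, and provenance (parameters + per-iteration residual
#'   norms).
#' @export
omp_detect_peaks <- function(mean_spec, mz_axis = attr(mean_spec, "mz"),
                             sigma, max_peaks = 500L, residual_tol = 0.02,
                             snr_min = 3, mode = "positive") {
  stopifnot(sigma > 0, max_peaks >= 1, residual_tol > 0, residual_tol < 1,
            snr_min >= 0)
  y <- as.numeric(mean_spec)
  n <- length(y)
  if (length(mz_axis) != n) stop_ovimsi("mz_axis length mismatch")
  y_norm <- sqrt(sum(y^2))
  if (y_norm == 0)
    return(new_peak_set(data.frame(center = numeric(), lo = numeric(),
                                   hi = numeric(), coefficient = numeric()),
                        sigma, mode, list(residual_norms = numeric())))

  step <- stats::median(diff(mz_axis))
  h <- ceiling(4 * sigma / step)
  kernel <- exp(-0.5 * ((-h:h) * step / sigma)^2)
  kernel <- kernel / sqrt(sum(kernel^2))
  # analytic Gram: inner product of two atoms offset by `lag` channels
  ac <- sapply(0:(2 * h), function(lag)
    sum(kernel[seq_len(2 * h + 1 - lag)] * kernel[seq_len(2 * h + 1 - lag) + lag]))
  gram <- function(lag) ifelse(lag > 2 * h, 0, ac[pmin(lag, 2 * h) + 1])

  xcorr <- function(v) {
    vp <- c(rep(0, h), v, rep(0, h))
    as.numeric(stats::filter(vp, kernel, sides = 2))[(h + 1):(h + n)]
  }
  b_full <- xcorr(y)        # atom-spectrum inner products (fixed)
  corr <- b_full            # atom-residual inner products (updated)
  # peaks are sparse, so the median/MAD of the atom correlations estimate
  # the level and spread a pure-noise atom reaches; both are ~0 for
  # noise-free spectra, deactivating the gate
  noise_gate <- stats::median(b_full) +
    snr_min * stats::mad(b_full, center = stats::median(b_full))
  selected <- integer(0)
  L <- matrix(0, 0, 0)      # Cholesky factor of the active Gram
  coef <- numeric(0)
  res_norms <- y_norm
  blocked <- rep(FALSE, n)

  repeat {
    corr_eff <- ifelse(blocked, -Inf, corr)
    j <- which.max(corr_eff)
    if (!is.finite(corr_eff[j]) || corr_eff[j] <= 0) break
    if (corr_eff[j] < noise_gate) break
    g_new <- gram(abs(j - selected))
    if (length(selected) == 0) {
      L_new <- matrix(1, 1, 1)
    } else {
      w <- forwardsolve(L, g_new)
      d2 <- 1 - sum(w^2)
      if (d2 <= 1e-10) { blocked[j] <- TRUE; next }  # near-collinear atom
      L_new <- rbind(cbind(L, 0), c(w, sqrt(d2)))
    }
    L <- L_new
    selected <- c(selected, j)
    blocked[j] <- TRUE
    coef <- backsolve(t(L), forwardsolve(L, b_full[selected]))
    # residual and its correlations, via the fitted sparse model
    fit <- numeric(n)
    for (k in seq_along(selected)) {
      jj <- max(1, selected[k] - h):min(n, selected[k] + h)
      fit[jj] <- fit[jj] + coef[k] * kernel[jj - selected[k] + h + 1]
    }
    r <- y - fit
    rn <- sqrt(sum(r^2))
    if (rn > res_norms[length(res_norms)] + 1e-9 * y_norm)
      stop_ovimsi("OMP residual increased; numerical failure")
    res_norms <- c(res_norms, rn)
    if (rn / y_norm <= residual_tol || length(selected) >= max_peaks) break
    corr <- xcorr(r)
  }

  keep <- coef > 0
  sel <- selected[keep]
  coef <- coef[keep]
  ord <- order(sel)
  sel <- sel[ord]; coef <- coef[ord]
  # a peak centered between two channels is represented by adjacent atoms,
  # and discretization mismatch can add small shoulder atoms; consolidate
  # chains of atoms closer than 3 sigma (unresolvable at this width) into
  # one peak whose center is the coefficient-weighted mean — the
  # sub-channel estimate the centroid step then refines on the spectrum
  if (length(sel) > 1) {
    grp <- cumsum(c(1, diff(mz_axis[sel]) > 3 * sigma))
    centers <- vapply(split(seq_along(sel), grp), function(i)
      sum(mz_axis[sel[i]] * coef[i]) / sum(coef[i]), numeric(1))
    coef <- vapply(split(coef, grp), sum, numeric(1))
  } else {
    centers <- mz_axis[sel]
  }
  lo <- centers - 3 * sigma
  hi <- centers + 3 * sigma
  if (length(centers) > 1) {
    mid <- (centers[-1] + centers[-length(centers)]) / 2
    hi[-length(hi)] <- pmin(hi[-length(hi)], mid)
    lo[-1] <- pmax(lo[-1], mid)
  }
  lo <- pmax(lo, mz_axis[1])
  hi <- pmin(hi, mz_axis[n])

  # centroid alignment to the mean spectrum, in a +/- 2 sigma window around
  # the atom center (clipped to the interval) so neighboring peaks and any
  # residual pedestal in the tails do not pull the center
  centroids <- vapply(seq_along(centers), function(k) {
    jj <- which(mz_axis >= max(lo[k], centers[k] - 2 * sigma) &
                  mz_axis <= min(hi[k], centers[k] + 2 * sigma))
    w <- y[jj]
    if (sum(w) <= 0) centers[k] else sum(mz_axis[jj] * w) / sum(w)
  }, numeric(1))

  new_peak_set(
    data.frame(center = centroids, lo = lo, hi = hi, coefficient = coef),
    sigma, mode,
    list(max_peaks = max_peaks, residual_tol = residual_tol,
         residual_norms = res_norms))
}

new_peak_set <- function(peaks, sigma, mode, provenance) {
  structure(list(peaks = peaks, sigma = sigma, mode = mode,
                 provenance = provenance),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks (sigma %.3g Th, %s mode)\n",
              nrow(x$peaks), x$sigma, x$mode))
  invisible(x)
}

#' Number of peaks in a peak set
#' @param x A `peak_set`.
#' @return Integer count.
#' @export
n_peaks <- function(x) nrow(x$peaks)

#' Extract per-spot peak intensities
#'
#' For every spot and peak interval: locate the local maximum within the
#' interval, compute the intensity-weighted centroid in a window of
#' `+/- sigma` around it, and — if that centroid falls inside the interval
#' (centroid matching) — record the summed intensity over the interval;
#' otherwise record 0.
#'
#' @param datasets A single preprocessed `ion_image_dataset` or a list.
#' @param peak_set A `peak_set` from [omp_detect_peaks()].
#' @return A `feature_table`: `spots` (sample/group/timepoint/mode/x/y per
#'   row), `peaks` (the peak set), `values`
#'   (nonnegative spots x peaks matrix).
#' @export
extract_features <- function(datasets, peak_set) {
  datasets <- as_dataset_list(datasets)
  mz <- shared_axis(datasets)
  pk <- peak_set$peaks
  if (nrow(pk) > 0 && (min(pk$lo) < mz[1] - 1e-9 || max(pk$hi) > mz[length(mz)] + 1e-9))
    stop_ovimsi("peak interval outside the m/z axis")
  step <- stats::median(diff(mz))
  wh <- max(1L, round(peak_set$sigma / step))

  per_dataset <- lapply(datasets, function(d) {
    X <- d$intensities
    ns <- nrow(X)
    vals <- matrix(0, ns, nrow(pk))
    for (k in seq_len(nrow(pk))) {
      jj <- which(mz >= pk$lo[k] & mz <= pk$hi[k])
      sub <- X[, jj, drop = FALSE]
      imax <- jj[max.col(sub, ties.method = "first")]
      offs <- -wh:wh
      idx <- pmin(pmax(rep(imax, each = length(offs)) + offs, 1L), length(mz))
      idx <- matrix(idx, nrow = length(offs))
      wts <- matrix(X[cbind(rep(seq_len(ns), each = length(offs)),
                            as.vector(idx))], nrow = length(offs))
      mzm <- matrix(mz[idx], nrow = length(offs))
      tot <- colSums(wts)
      centroid <- ifelse(tot > 0, colSums(mzm * wts) / tot, mz[imax])
      ok <- centroid >= pk$lo[k] & centroid <= pk$hi[k]
      vals[ok, k] <- rowSums(sub)[ok]
    }
    spots <- data.frame(sample_id = d$sample_id, group = d$group,
                        timepoint = d$timepoint, mode = d$mode,
                        x = d$coords$x, y = d$coords$y)
    list(spots = spots, vals = vals)
  })

  structure(list(
    spots = do.call(rbind, lapply(per_dataset, `[[`, "spots")),
    peaks = peak_set,
    values = do.call(rbind, lapply(per_dataset, `[[`, "vals"))),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d spots (%d sample(s)) x %d peaks\n",
              nrow(x$spots), length(unique(x$spots$sample_id)),
              ncol(x$values)))
  invisible(x)
}

#' Rows of a feature table inside an ROI mask
#'
#' Maps a grid-level ROI mask onto feature-table rows by (x, y) coordinate,
#' for all samples present (all sections share the grid geometry).
#'
#' @param table A `feature_table`.
#' @param roi A [roi_mask()] or a logical vector aligned to the table rows.
#' @return Logical vector over table rows.
#' @export
table_roi_rows <- function(table, roi) {
  if (is.logical(roi)) {
    if (length(roi) != nrow(table$spots))
      stop_ovimsi("logical ROI length must match table rows")
    return(roi)
  }
  stopifnot(inherits(roi, "roi_mask"))
  on_keys <- with(roi$coords[roi$mask, , drop = FALSE], paste(x, y))
  paste(table$spots$x, table$spots$y) %in% on_keys
}

#' Average peak intensity over an ROI
#'
#' Mean of the feature-table values over (ROI spots x all peaks) — the
#' single-number intensity summary compared between diet groups.
#'
#' @param table A `feature_table`.
#' @param roi A [roi_mask()] or logical row selector.
#' @return Scalar mean intensity.
#' @export
average_peak_intensity <- function(table, roi) {
  rows <- table_roi_rows(table, roi)
  if (!any(rows)) stop_ovimsi("ROI selects no spots")
  mean(table$values[rows, , drop = FALSE])
}

#' Subset a feature table
#'
#' @param table A `feature_table`.
#' @param rows Logical or integer row selector over spots.
#' @return The subsetted `feature_table`.
#' @export
subset_table <- function(table, rows) {
  structure(list(spots = table$spots[rows, , drop = FALSE],
                 peaks = table$peaks,
                 values = table$values[rows, , drop = FALSE]),
            class = "feature_table")
}
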