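# Spectrum preprocessing: mass filters (low-mass deflection + exclusion
# windows), Tophat morphological baseline correction, and per-spot TIC
# normalization. The pipeline order is fixed as filter -> baseline ->
# normalize: excluding the matrix-cluster window before TIC prevents matrix
# signal from dominating the normalization, and normalization must see the
# analyzed (filtered, baseline-corrected) range only.

#' Preprocessing parameters
#'
#' @param tophat_width Width of the flat structuring element in channels;
#'   odd, at least 3. Default 29 channels, about five times the synthetic
#'   peak FWHM at the default axis spacing — wide enough to pass isolated
#'   peaks through untouched while removing slowly varying background.
#' @param tic_target `"unit_sum"` (each spot sums to 1) or `"mean_tic"`
#'   (each spot sums to the pre-normalization mean TIC).
#' @param deflect_below Remove channels below this m/z (default 400,
#'   mirroring the instrument's low-mass deflection).
#' @param exclusion_windows List of `c(low, high)` m/z windows to remove;
#'   default `list(c(493, 507))`, the matrix-cluster interval centered at
#'   m/z 500 with total width 14.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(tophat_width = 29L,
                              tic_target = c("unit_sum", "mean_tic"),
                              deflect_below = 400,
                              exclusion_windows = list(c(493, 507))) {
  tic_target <- match.arg(tic_target)
  check_tophat_width(tophat_width)
  for (w in exclusion_windows) {
    if (length(w) != 2 || w[1] >= w[2])
      stop_ovimsi("exclusion window must be c(low, high) with low < high")
    if (w[1] < 400 || w[2] > 2000)
      stop_ovimsi("exclusion windows must lie within m/z [400, 2000]")
  }
  structure(list(tophat_width = as.integer(tophat_width),
                 tic_target = tic_target,
                 deflect_below = deflect_below,
                 exclusion_windows = exclusion_windows),
            class = "preprocess_params")
}

check_tophat_width <- function(width, n = NULL) {
  if (length(width) != 1 || is.na(width) || width < 3 || width %% 2 == 0)
    stop_ovimsi("tophat width must be an odd integer >= 3")
  if (!is.null(n) && width > n)
    stop_ovimsi("tophat width (", width, ") exceeds spectrum length (", n, ")")
  invisible(width)
}

#' Tophat baseline correction of a single spectrum
#'
#' Subtracts the morphological opening (erosion then dilation with a flat
#' structuring element) from the spectrum. The opening is the widest
#' slowly varying lower envelope, so subtraction removes baseline drift
#' while preserving peaks narrower than the structuring element. The result
#' is nonnegative and never exceeds the input.
#'
#' @param spectrum Numeric intensity vector.
#' @param width Structuring element width in channels (odd, >= 3, at most
#'   the spectrum length).
#' @return Corrected intensity vector.
#' @export
tophat_baseline_correct <- function(spectrum, width) {
  check_tophat_width(width, length(spectrum))
  as.numeric(.tophat_rows(matrix(as.numeric(spectrum), nrow = 1), as.integer(width)))
}

#' Tophat baseline correction of every spot of a dataset
#'
#' @param dataset An `ion_image_dataset`.
#' @param width Structuring element width in channels.
#' @return The dataset with corrected intensities.
#' @export
tophat_correct_dataset <- function(dataset, width) {
  check_tophat_width(width, length(dataset$mz))
  dataset$intensities <- .tophat_rows(dataset$intensities, as.integer(width))
  dataset
}

#' TIC normalization
#'
#' Rescales each spot so its total ion count (channel sum) equals 1
#' (`unit_sum`) or the pre-normalization mean TIC over spots (`mean_tic`).
#' Within-spot peak ratios are unchanged. Spots with zero TIC cannot be
#' normalized; they are dropped with a warning, never imputed.
#'
#' @param dataset An `ion_image_dataset` (normally baseline-corrected).
#' @param target `"unit_sum"` or `"mean_tic"`.
#' @return The normalized dataset (possibly with fewer spots).
#' @export
tic_normalize <- function(dataset, target = c("unit_sum", "mean_tic")) {
  target <- match.arg(target)
  tic <- rowSums(dataset$intensities)
  zero <- tic <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-TIC spot(s) dropped during normalization",
            call. = FALSE)
    dataset$intensities <- dataset$intensities[!zero, , drop = FALSE]
    dataset$coords <- dataset$coords[!zero, , drop = FALSE]
    tic <- tic[!zero]
    if (!length(tic)) stop_ovimsi("all spots have zero TIC")
  }
  scale_to <- if (target == "unit_sum") 1 else mean(tic)
  dataset$intensities <- dataset$intensities * (scale_to / tic)
  dataset
}

#' Low-mass deflection and exclusion windows
#'
#' Removes channels below `deflect_below` and channels inside any exclusion
#' window, keeping the m/z axis and intensity matrix consistent.
#'
#' @param dataset An `ion_image_dataset`.
#' @param params A [preprocess_params()].
#' @return The filtered dataset; an attribute `"channels_removed"` records
#'   how many channels each filter removed.
#' @export
apply_mass_filters <- function(dataset, params) {
  keep <- dataset$mz >= params$deflect_below
  n_deflected <- sum(!keep)
  excluded <- rep(FALSE, length(dataset$mz))
  for (w in params$exclusion_windows)
    excluded <- excluded | (dataset$mz >= w[1] & dataset$mz <= w[2])
  n_excluded <- sum(excluded & keep)
  keep <- keep & !excluded
  if (!any(keep))
    stop_ovimsi("mass filters removed every channel")
  dataset$mz <- dataset$mz[keep]
  dataset$intensities <- dataset$intensities[, keep, drop = FALSE]
  attr(dataset, "channels_removed") <-
    c(deflection = n_deflected, exclusion = n_excluded)
  dataset
}

#' Full preprocessing of one dataset
#'
#' Applies the three steps in the pipeline's fixed order: mass filters
#' (deflection + exclusion windows), then Tophat baseline correction, then
#' TIC normalization. The order matters — the TIC depends on which channels
#' are retained — so it is enforced here rather than left to callers.
#'
#' @param dataset An `ion_image_dataset`.
#' @param params A [preprocess_params()].
#' @return The preprocessed dataset; attribute `"preprocess_log"` records
#'   the step order and channel/spot counts.
#' @export
preprocess_dataset <- function(dataset, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  n0 <- length(dataset$mz); s0 <- n_spots(dataset)
  dataset <- apply_mass_filters(dataset, params)
  removed <- attr(dataset, "channels_removed")
  dataset <- tophat_correct_dataset(dataset, params$tophat_width)
  dataset <- tic_normalize(dataset, params$tic_target)
  attr(dataset, "preprocess_log") <- list(
    order = c("mass_filters", "tophat", "tic_normalize"),
    channels_in = n0, channels_out = length(dataset$mz),
    channels_removed = removed,
    spots_in = s0, spots_out = n_spots(dataset),
    tophat_width = params$tophat_width, tic_target = params$tic_target)
  dataset
}
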