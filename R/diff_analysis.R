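# Bidirectional ROC analysis of ROI spectra: per-peak AUC between diet
# groups, discriminative-mass (DM) calling at a threshold, summary tables in
# the per-time-point layout, cross-time-point overlap, and DM intensity
# distributions.
#
# Direction semantics: an AUC >= threshold in the HFHS-vs-CTRL analysis means
# the mass is more abundant in HFHS; the complementary direction (CTRL vs
# HFHS, i.e., 1 - AUC >= threshold) means more abundant in CTRL. Testing both
# directions avoids biasing detection toward abundant masses. No
# multiple-testing correction is applied — calling is by the AUC threshold
# alone, and ROI spots are pooled across the sections of a group (spectra,
# not animals, are the observational units; see the methods vignette for the
# pseudoreplication caveat and the per-sample-mean alternative).

#' ROC area under the curve
#'
#' Probability that a random positive exceeds a random negative, with ties
#' half-credited (the Mann-Whitney convention):
#' `AUC = (#\{p > n\} + 0.5 #\{p = n\}) / (|P| |N|)`, computed via rank sums.
#'
#' @param positives,negatives Nonempty numeric intensity vectors.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(positives, negatives) {
  np <- length(positives); nn <- length(negatives)
  if (np == 0 || nn == 0) stop_ovimsi("both groups must be nonempty")
  r <- rank(c(positives, negatives))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Detect discriminative masses by bidirectional ROC
#'
#' For every peak of a feature table: pool the ROI spot intensities of each
#' diet group (across that group's sections), compute the HFHS-vs-CTRL AUC,
#' and call the peak discriminative in the HFHS_vs_CTRL direction if
#' `AUC >= threshold` or in the CTRL_vs_HFHS direction if
#' `1 - AUC >= threshold`. With `threshold > 0.5` at most one direction can
#' fire per peak.
#'
#' @param table A `feature_table` containing both groups of one
#'   (time point, mode) batch.
#' @param roi A [roi_mask()] (applied to every section by grid coordinates)
#'   or a logical row selector.
#' @param threshold AUC calling threshold in `(0.5, 1]`; default 0.7.
#' @param by_sample_mean If `TRUE`, average ROI spots within each section
#'   first and run the ROC on section means (the conservative alternative
#'   to pooling spectra).
#' @return Data frame of class `dm_table`: `center_mz`, `auc` (in the called
#'   direction), `direction`, `mode`, `timepoint`, `peak` (column index).
#' @export
detect_dms <- function(table, roi, threshold = 0.7, by_sample_mean = FALSE) {
  if (threshold <= 0.5 || threshold > 1)
    stop_ovimsi("threshold must be in (0.5, 1]")
  rows <- table_roi_rows(table, roi)
  spots <- table$spots
  for (sid in unique(spots$sample_id))
    if (!any(rows & spots$sample_id == sid))
      stop_ovimsi("ROI is empty for sample ", sid)
  groups <- unique(spots$group)
  if (!all(c("CTRL", "HFHS") %in% groups))
    stop_ovimsi("both CTRL and HFHS must be present")

  vals <- table$values[rows, , drop = FALSE]
  grp <- spots$group[rows]
  if (by_sample_mean) {
    sid <- spots$sample_id[rows]
    vals <- do.call(rbind, lapply(split(seq_along(sid), sid), function(i)
      colMeans(vals[i, , drop = FALSE])))
    grp <- vapply(split(grp, sid), `[`, character(1), 1)
  }
  pos <- grp == "HFHS"

  pk <- table$peaks$peaks
  res <- lapply(seq_len(ncol(vals)), function(k) {
    auc_h <- roc_auc(vals[pos, k], vals[!pos, k])
    if (auc_h >= threshold)
      data.frame(center_mz = pk$center[k], auc = auc_h,
                 direction = "HFHS_vs_CTRL", peak = k)
    else if (1 - auc_h >= threshold)
      data.frame(center_mz = pk$center[k], auc = 1 - auc_h,
                 direction = "CTRL_vs_HFHS", peak = k)
    else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(center_mz = numeric(), auc = numeric(),
                      direction = character(), peak = integer())
  out$mode <- if (nrow(out)) spots$mode[1] else character(0)
  out$timepoint <- if (nrow(out)) spots$timepoint[1] else character(0)
  rownames(out) <- NULL
  class(out) <- c("dm_table", "data.frame")
  out
}

#' Summarize discriminative-mass counts
#'
#' Produces the per-time-point layout used to report DM counts: one row per
#' time point with counts per (mode x direction) cell, per-direction totals,
#' and the overall total.
#'
#' @param dms A `dm_table` (or any data frame with `timepoint`, `mode`,
#'   `direction`), or a list of them which are row-bound first.
#' @return Data frame of class `dm_summary`.
#' @export
summarize_dms <- function(dms) {
  if (is.data.frame(dms)) dms <- list(dms)
  dms <- do.call(rbind, lapply(dms, function(d)
    as.data.frame(d)[, c("timepoint", "mode", "direction"), drop = FALSE]))
  if (is.null(dms) || nrow(dms) == 0)
    return(dm_summary_from_counts(
      data.frame(timepoint = character(), mode = character(),
                 direction = character(), count = integer())))
  counts <- as.data.frame(table(timepoint = dms$timepoint, mode = dms$mode,
                                direction = dms$direction),
                          responseName = "count", stringsAsFactors = FALSE)
  dm_summary_from_counts(counts)
}

#' Build a DM summary from per-cell counts
#'
#' The same layout as [summarize_dms()], but starting from already-tabulated
#' counts per (time point, mode, direction) — e.g., a published count table
#' whose row totals are to be recomputed.
#'
#' @param counts Data frame with `timepoint`, `mode`, `direction`, `count`.
#' @return Data frame of class `dm_summary`: per time point, the four
#'   (mode x direction) cells, `total_HFHS_vs_CTRL`, `total_CTRL_vs_HFHS`,
#'   and `total_dms`; totals equal the sums of their components.
#' @export
dm_summary_from_counts <- function(counts) {
  tps <- intersect(TIMEPOINT_LEVELS, unique(counts$timepoint))
  cell <- function(tp, mode, dir) {
    sum(counts$count[counts$timepoint == tp & counts$mode == mode &
                       counts$direction == dir])
  }
  out <- do.call(rbind, lapply(tps, function(tp) {
    nh <- cell(tp, "negative", "HFHS_vs_CTRL")
    nc <- cell(tp, "negative", "CTRL_vs_HFHS")
    ph <- cell(tp, "positive", "HFHS_vs_CTRL")
    pc <- cell(tp, "positive", "CTRL_vs_HFHS")
    data.frame(timepoint = tp,
               negative_HFHS_vs_CTRL = nh, negative_CTRL_vs_HFHS = nc,
               positive_HFHS_vs_CTRL = ph, positive_CTRL_vs_HFHS = pc,
               total_HFHS_vs_CTRL = nh + ph, total_CTRL_vs_HFHS = nc + pc,
               total_dms = nh + nc + ph + pc)
  }))
  if (is.null(out))
    out <- data.frame(timepoint = character(),
                      negative_HFHS_vs_CTRL = integer(),
                      negative_CTRL_vs_HFHS = integer(),
                      positive_HFHS_vs_CTRL = integer(),
                      positive_CTRL_vs_HFHS = integer(),
                      total_HFHS_vs_CTRL = integer(),
                      total_CTRL_vs_HFHS = integer(), total_dms = integer())
  rownames(out) <- NULL
  class(out) <- c("dm_summary", "data.frame")
  out
}

#' Match discriminative masses across time points
#'
#' Greedy nearest-first pairing of DM centers from two lists within an m/z
#' tolerance, same ionization mode only; each DM is matched at most once.
#'
#' @param dms_a,dms_b `dm_table` data frames.
#' @param mz_tol Matching tolerance in Thomson (default 0.1).
#' @return Data frame of matched pairs: indexes into both inputs, both
#'   centers, and the m/z difference.
#' @export
overlap_dms <- function(dms_a, dms_b, mz_tol = 0.1) {
  if (mz_tol <= 0) stop_ovimsi("mz_tol must be positive")
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      center_a = numeric(), center_b = numeric(),
                      delta_mz = numeric())
  if (nrow(dms_a) == 0 || nrow(dms_b) == 0) return(empty)
  cand <- expand.grid(idx_a = seq_len(nrow(dms_a)), idx_b = seq_len(nrow(dms_b)))
  cand <- cand[dms_a$mode[cand$idx_a] == dms_b$mode[cand$idx_b], , drop = FALSE]
  cand$delta_mz <- dms_a$center_mz[cand$idx_a] - dms_b$center_mz[cand$idx_b]
  cand <- cand[abs(cand$delta_mz) <= mz_tol, , drop = FALSE]
  cand <- cand[order(abs(cand$delta_mz)), , drop = FALSE]
  used_a <- logical(nrow(dms_a)); used_b <- logical(nrow(dms_b))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand$idx_a[i]; b <- cand$idx_b[i]
    if (!used_a[a] && !used_b[b]) {
      keep[i] <- TRUE; used_a[a] <- TRUE; used_b[b] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out$center_a <- dms_a$center_mz[out$idx_a]
  out$center_b <- dms_b$center_mz[out$idx_b]
  rownames(out) <- NULL
  out[, c("idx_a", "idx_b", "center_a", "center_b", "delta_mz")]
}

#' Per-spot mean intensity over the DMs of one direction
#'
#' For every ROI spot, the mean feature intensity over the DM peaks called
#' in the given direction — the per-group distributions behind a DM
#' intensity boxplot.
#'
#' @param table A `feature_table`.
#' @param roi A [roi_mask()] or logical row selector.
#' @param dms A `dm_table` with a `peak` column indexing the table's peaks.
#' @param direction `"HFHS_vs_CTRL"` or `"CTRL_vs_HFHS"`.
#' @return Data frame: sample, group, spot coordinates, `mean_intensity`.
#' @export
dm_intensity_summary <- function(table, roi, dms,
                                 direction = c("HFHS_vs_CTRL", "CTRL_vs_HFHS")) {
  direction <- match.arg(direction)
  if (nrow(dms) == 0) stop_ovimsi("no discriminative masses supplied")
  cols <- dms$peak[dms$direction == direction]
  if (!length(cols))
    stop_ovimsi("no discriminative masses in direction ", direction)
  rows <- table_roi_rows(table, roi)
  if (!any(rows)) stop_ovimsi("ROI selects no spots")
  out <- table$spots[rows, c("sample_id", "group", "x", "y")]
  out$mean_intensity <- rowMeans(table$values[rows, cols, drop = FALSE])
  rownames(out) <- NULL
  out
}
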