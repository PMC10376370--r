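# End-to-end orchestration: from a config (synthetic study or imzML file
# manifest) through preprocessing, peak detection, segmentation, ROI
# selection, DM detection and annotation, per (time point, mode) batch —
# control and HFHS sections of a batch are always analyzed together — with
# all report tables written to an output directory and a JSON run log
# recording every parameter and seed. Reruns with an identical config are
# bit-identical.

#' Pipeline configuration
#'
#' Exactly one input source must be given: a synthetic study (config +
#' seed) or an input manifest of imzML samples with a reference mask.
#'
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param synthetic_seed Seed for the synthetic study.
#' @param input_manifest `NULL`, or a list with `imzml_paths` (character
#'   vector; JSON sidecars supply metadata) and `mask_path` (TSV with
#'   columns x, y, mask).
#' @param preprocess A [preprocess_params()].
#' @param omp_sigma Gaussian atom width for peak detection (Thomson); for
#'   synthetic input, defaults to the generator's peak sigma.
#' @param omp_max_peaks,omp_residual_tol,omp_snr_min OMP stopping
#'   parameters (see [omp_detect_peaks()]).
#' @param segmentation_depth,segmentation_seed,segmentation_restarts
#'   Bisecting k-means parameters (depth default 3; per-split dispersions
#'   are reported so the depth can be revised from the diagnostics).
#' @param roc_threshold AUC calling threshold, in `(0.5, 1]`.
#' @param annotation_tolerance Mass tolerance (Da) for putative annotation.
#' @param out_dir Output directory for report tables; `NULL` for none.
#' @param make_plots Write PNG ion-density/segmentation maps.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, synthetic_seed = 1L,
                            input_manifest = NULL,
                            preprocess = preprocess_params(),
                            omp_sigma = NULL, omp_max_peaks = 500L,
                            omp_residual_tol = 0.02, omp_snr_min = 3,
                            segmentation_depth = 3L,
                            segmentation_seed = 1L,
                            segmentation_restarts = 5L,
                            roc_threshold = 0.7,
                            annotation_tolerance = 0.05,
                            out_dir = NULL, make_plots = FALSE) {
  if (is.null(synthetic) == is.null(input_manifest))
    stop_ovimsi("exactly one of `synthetic` / `input_manifest` must be given")
  if (roc_threshold <= 0.5 || roc_threshold > 1)
    stop_ovimsi("roc_threshold must be in (0.5, 1]")
  if (is.null(omp_sigma)) {
    if (!is.null(synthetic)) omp_sigma <- synthetic$sigma_peak
    else stop_ovimsi("omp_sigma must be given for imzML input")
  }
  structure(list(synthetic = synthetic, synthetic_seed = as.integer(synthetic_seed),
                 input_manifest = input_manifest, preprocess = preprocess,
                 omp_sigma = omp_sigma, omp_max_peaks = as.integer(omp_max_peaks),
                 omp_residual_tol = omp_residual_tol, omp_snr_min = omp_snr_min,
                 segmentation_depth = as.integer(segmentation_depth),
                 segmentation_seed = as.integer(segmentation_seed),
                 segmentation_restarts = as.integer(segmentation_restarts),
                 roc_threshold = roc_threshold,
                 annotation_tolerance = annotation_tolerance,
                 out_dir = out_dir, make_plots = isTRUE(make_plots)),
            class = "pipeline_config")
}

#' Analyze one (time point, mode) batch
#'
#' The per-batch core of the pipeline: preprocess every section, detect
#' peaks on the pooled mean spectrum, extract features, segment each
#' section and select its epithelium ROI against the reference mask, run
#' bidirectional ROC DM detection on the pooled ROI spots, and compute the
#' per-group skyline spectra and average ROI peak intensities.
#'
#' @param datasets List of `ion_image_dataset` of one time point and mode
#'   (both groups).
#' @param reference A [roi_mask()] reference (epithelium) mask.
#' @param config A [pipeline_config()].
#' @return List: `peaks`, `table`, `segmentations`, `rois` (per sample),
#'   `roi_rows`, `dms`, `avg_intensity` (per group), `skylines` (per
#'   group), `preprocess_logs`.
#' @export
analyze_batch <- function(datasets, reference, config) {
  prep <- lapply(datasets, preprocess_dataset, params = config$preprocess)
  logs <- lapply(prep, attr, "preprocess_log")
  ms <- mean_spectrum(prep)
  # averaging zero-clipped noise leaves a positive pedestal on the mean
  # spectrum; remove it with the same Tophat filter before peak picking so
  # the OMP residual criterion sees peaks, not the pedestal
  ms_corr <- tophat_baseline_correct(ms, config$preprocess$tophat_width)
  attr(ms_corr, "mz") <- attr(ms, "mz")
  pk <- omp_detect_peaks(ms_corr, sigma = config$omp_sigma,
                         max_peaks = config$omp_max_peaks,
                         residual_tol = config$omp_residual_tol,
                         snr_min = config$omp_snr_min,
                         mode = prep[[1]]$mode)
  tab <- extract_features(prep, pk)

  sample_ids <- unique(tab$spots$sample_id)
  segmentations <- list(); rois <- list()
  roi_rows <- rep(FALSE, nrow(tab$spots))
  for (sid in sample_ids) {
    rows <- tab$spots$sample_id == sid
    sub <- subset_table(tab, rows)
    seg <- bisecting_kmeans(sub, depth = config$segmentation_depth,
                            seed = config$segmentation_seed,
                            restarts = config$segmentation_restarts)
    roi <- select_roi(seg, reference)
    segmentations[[sid]] <- seg
    rois[[sid]] <- roi
    roi_rows[rows] <- roi$mask
  }

  dms <- detect_dms(tab, roi_rows, threshold = config$roc_threshold)
  groups <- unique(tab$spots$group)
  avg <- vapply(groups, function(g)
    average_peak_intensity(tab, roi_rows & tab$spots$group == g), numeric(1))
  skylines <- lapply(setNames(groups, groups), function(g)
    skyline_spectrum(prep[vapply(prep, function(d) d$group == g, logical(1))]))

  list(peaks = pk, table = tab, segmentations = segmentations, rois = rois,
       roi_rows = roi_rows, dms = dms,
       avg_intensity = setNames(avg, groups), skylines = skylines,
       preprocess_logs = logs)
}

load_input_manifest <- function(man) {
  datasets <- lapply(man$imzml_paths, read_imzml)
  names(datasets) <- vapply(datasets, function(d)
    paste(d$sample_id, d$mode, sep = "_"), character(1))
  m <- read.table(man$mask_path, header = TRUE, sep = "\t")
  reference <- roi_mask(m[, c("x", "y")], as.logical(m$mask),
                        source = "reference")
  list(datasets = datasets, reference = reference, manifest = NULL)
}

#' Run a full study analysis
#'
#' Generates (or reads) the study's datasets, runs [analyze_batch()] for
#' every (time point, mode) combination present, and aggregates: the DM
#' count summary, putative lipid-class categories, cross-time-point DM
#' overlap counts, and the per-batch average ROI intensities. When
#' `config$out_dir` is set, all tables are written as TSV/CSV plus a JSON
#' run log of every parameter and seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `study_report`: `batches` (per time point x mode),
#'   `dms` (all DMs, annotated), `dm_summary`, `class_summary`,
#'   `overlap` (pairwise common-DM counts between time points per mode),
#'   `avg_intensity`, `manifest` (ground truth, synthetic input only),
#'   `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$synthetic)) {
    study <- generate_study(config$synthetic, config$synthetic_seed)
    datasets <- study$datasets
    reference <- reference_mask(study$manifest)
    manifest <- study$manifest
  } else {
    inp <- load_input_manifest(config$input_manifest)
    datasets <- inp$datasets; reference <- inp$reference; manifest <- NULL
  }

  key <- vapply(datasets, function(d) paste(d$timepoint, d$mode, sep = "|"),
                character(1))
  batches <- list()
  all_dms <- list()
  avg_rows <- list()
  for (k in unique(key)) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    batch <- analyze_batch(datasets[key == k], reference, config)
    batches[[k]] <- batch
    all_dms[[k]] <- batch$dms
    avg_rows[[k]] <- data.frame(timepoint = parts[1], mode = parts[2],
                                group = names(batch$avg_intensity),
                                mean_intensity = unname(batch$avg_intensity))
  }
  dms <- do.call(rbind, all_dms)
  rownames(dms) <- NULL
  db <- build_lipid_db()
  dms <- if (nrow(dms)) annotate_dms(dms, db, config$annotation_tolerance)
         else cbind(dms, data.frame(category = character(),
                                    n_candidates = integer()))
  summary_tab <- summarize_dms(dms)
  class_tab <- summarize_classes(dms)
  avg_tab <- do.call(rbind, avg_rows)
  rownames(avg_tab) <- NULL

  # pairwise common-DM counts between time points, per mode
  overlap <- list()
  for (mode in unique(dms$mode)) {
    tps <- intersect(TIMEPOINT_LEVELS, unique(dms$timepoint[dms$mode == mode]))
    mat <- matrix(0L, length(tps), length(tps), dimnames = list(tps, tps))
    for (i in seq_along(tps)) for (j in seq_along(tps)) {
      a <- dms[dms$mode == mode & dms$timepoint == tps[i], , drop = FALSE]
      b <- dms[dms$mode == mode & dms$timepoint == tps[j], , drop = FALSE]
      mat[i, j] <- if (i == j) nrow(a) else nrow(overlap_dms(a, b))
    }
    overlap[[mode]] <- mat
  }

  report <- structure(
    list(batches = batches, dms = dms, dm_summary = summary_tab,
         class_summary = class_tab, overlap = overlap,
         avg_intensity = avg_tab, manifest = manifest, config = config),
    class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d batch(es), %d discriminative masses\n",
              length(x$batches), nrow(x$dms)))
  print(x$dm_summary)
  invisible(x)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  for (k in names(report$batches)) {
    b <- report$batches[[k]]
    tag <- gsub("|", "_", k, fixed = TRUE)
    write_tsv(b$peaks$peaks, file.path(out_dir, paste0("peaks_", tag, ".tsv")))
    for (sid in names(b$segmentations)) {
      seg <- b$segmentations[[sid]]
      write_tsv(data.frame(seg$spots[, c("x", "y")], label = seg$labels),
                file.path(out_dir, paste0("segmentation_", tag, "_", sid, ".tsv")))
      roi <- b$rois[[sid]]
      write_tsv(data.frame(roi$coords, mask = roi$mask),
                file.path(out_dir, paste0("roi_", tag, "_", sid, ".tsv")))
    }
    for (g in names(b$skylines)) {
      sky <- b$skylines[[g]]
      write_tsv(data.frame(mz = attr(sky, "mz"), intensity = as.numeric(sky)),
                file.path(out_dir, paste0("skyline_", tag, "_", g, ".tsv")))
    }
    if (cfg$make_plots && nrow(b$peaks$peaks)) {
      top <- which.max(b$peaks$peaks$coefficient)
      grDevices::png(file.path(out_dir, paste0("density_", tag, ".png")),
                     width = 600, height = 600)
      plot(ion_density_map_from_table(b$table, top))
      grDevices::dev.off()
    }
  }
  write_tsv(report$dms, file.path(out_dir, "dms_annotated.tsv"))
  utils::write.csv(report$dm_summary, file.path(out_dir, "dm_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$class_summary$counts,
                   file.path(out_dir, "class_categories.csv"), row.names = FALSE)
  utils::write.csv(report$avg_intensity,
                   file.path(out_dir, "avg_intensity.csv"), row.names = FALSE)
  for (mode in names(report$overlap))
    utils::write.csv(report$overlap[[mode]],
                     file.path(out_dir, paste0("dm_overlap_", mode, ".csv")))
  log <- list(
    timestamp = "fixed-for-reproducibility",
    synthetic_seed = cfg$synthetic_seed,
    segmentation = list(depth = cfg$segmentation_depth,
                        seed = cfg$segmentation_seed,
                        restarts = cfg$segmentation_restarts,
                        dispersion_trees = lapply(report$batches, function(b)
                          lapply(b$segmentations, `[[`, "tree"))),
    preprocess = unclass(cfg$preprocess),
    omp = list(sigma = cfg$omp_sigma, max_peaks = cfg$omp_max_peaks,
               residual_tol = cfg$omp_residual_tol, snr_min = cfg$omp_snr_min),
    roc_threshold = cfg$roc_threshold,
    annotation_tolerance = cfg$annotation_tolerance,
    batches = lapply(report$batches, function(b) b$preprocess_logs))
  jsonlite::write_json(log, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# per-spot aggregated intensity of one feature-table peak on the grid of the
# table's first sample
ion_density_map_from_table <- function(table, peak_index) {
  sid <- table$spots$sample_id[1]
  rows <- table$spots$sample_id == sid
  vals <- table$values[rows, peak_index]
  co <- table$spots[rows, c("x", "y")]
  img <- matrix(NA_real_, max(co$y) + 1L, max(co$x) + 1L)
  img[cbind(co$y + 1L, co$x + 1L)] <- vals
  pk <- table$peaks$peaks[peak_index, ]
  structure(img, class = c("ion_density_map", "matrix"),
            mz_interval = c(pk$lo, pk$hi))
}

#' Percent difference between two group means
#'
#' `100 * (mean_a - mean_b) / mean_b`, reported to one decimal — e.g., the
#' percent body-weight difference between diet groups at one time point.
#'
#' @param mean_a,mean_b Group means; `mean_b` is the reference and must be
#'   positive.
#' @return Percent difference, rounded to one decimal.
#' @export
#' @examples
#' percent_group_difference(48.30, 36.16)  # 33.6
percent_group_difference <- function(mean_a, mean_b) {
  if (mean_b <= 0) stop_ovimsi("reference mean must be positive")
  round(100 * (mean_a - mean_b) / mean_b, 1)
}

#' Percentage of a category count
#'
#' `100 * count / total`, to one decimal.
#'
#' @param count,total Nonnegative integers, `count <= total`, `total > 0`.
#' @return Percentage to one decimal.
#' @export
#' @examples
#' proportion_of_category(34, 119)  # 28.6
proportion_of_category <- function(count, total) {
  if (total <= 0) stop_ovimsi("total must be positive")
  if (count < 0 || count > total) stop_ovimsi("count must be in [0, total]")
  round(100 * count / total, 1)
}
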