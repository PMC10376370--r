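# TSV interchange for peak sets and feature tables — the on-disk formats the
# pipeline emits and the command-line verbs consume.

#' Write / read a peak set as TSV
#'
#' One row per peak (center, lo, hi, coefficient); the atom width and
#' ionization mode ride in a `#`-prefixed header line so a round trip
#' restores a usable `peak_set`.
#'
#' @param peak_set A `peak_set`.
#' @param path Output TSV path.
#' @return `path` (write) or a `peak_set` (read), invisibly for write.
#' @export
write_peak_set <- function(peak_set, path) {
  con <- file(path, "w")
  writeLines(sprintf("# oviMSI peak_set sigma=%.17g mode=%s",
                     peak_set$sigma, peak_set$mode), con)
  close(con)
  suppressWarnings(write.table(peak_set$peaks, path, sep = "\t",
                               quote = FALSE, row.names = FALSE,
                               append = TRUE))
  invisible(path)
}

parse_header <- function(path, what) {
  line <- readLines(path, n = 1)
  if (!startsWith(line, paste0("# oviMSI ", what)))
    stop_ovimsi(path, " is not an oviMSI ", what, " TSV")
  kv <- regmatches(line, gregexpr("[a-z_]+=[^ ]+", line))[[1]]
  vals <- sub("^[a-z_]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  vals
}

#' @rdname write_peak_set
#' @export
read_peak_set <- function(path) {
  hdr <- parse_header(path, "peak_set")
  peaks <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  new_peak_set(peaks, sigma = as.numeric(hdr[["sigma"]]),
               mode = hdr[["mode"]], provenance = list(source = path))
}

#' Write / read a feature table as TSV
#'
#' One row per spot: the label columns (sample, group, time point, mode,
#' grid x/y) followed by one intensity column per peak, named
#' `mz_<center>`. The peak geometry travels in a sibling peak-set TSV
#' (`<path>.peaks.tsv`).
#'
#' @param table A `feature_table`.
#' @param path Output TSV path.
#' @return `path` (write) or a `feature_table` (read), invisibly for write.
#' @export
write_feature_table <- function(table, path) {
  vals <- table$values
  colnames(vals) <- sprintf("mz_%.4f", table$peaks$peaks$center)
  write.table(cbind(table$spots, vals), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_peak_set(table$peaks, paste0(path, ".peaks.tsv"))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  label_cols <- c("sample_id", "group", "timepoint", "mode", "x", "y")
  if (!all(label_cols %in% names(d)))
    stop_ovimsi("feature table is missing label columns")
  pk <- read_peak_set(paste0(path, ".peaks.tsv"))
  vals <- as.matrix(d[, setdiff(names(d), label_cols), drop = FALSE])
  if (ncol(vals) != nrow(pk$peaks))
    stop_ovimsi("feature columns do not match the sibling peak set")
  dimnames(vals) <- NULL
  structure(list(spots = d[, label_cols], peaks = pk, values = vals),
            class = "feature_table")
}

#' Write / read an ROI mask as TSV
#'
#' @param roi A [roi_mask()].
#' @param path TSV path (columns x, y, mask).
#' @return `path` (write) or a `roi_mask` (read), invisibly for write.
#' @export
write_roi_mask <- function(roi, path) {
  write.table(data.frame(roi$coords, mask = roi$mask), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_mask
#' @param source Source tag to record on the read mask.
#' @export
read_roi_mask <- function(path, source = "reference") {
  d <- read.table(path, header = TRUE, sep = "\t")
  roi_mask(d[, c("x", "y")], as.logical(d$mask), source = source)
}
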