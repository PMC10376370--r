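# Spatial segmentation by bisecting k-means under the Manhattan (L1) metric,
# ROI selection against a reference mask, and ion density maps.
#
# The L1 2-means split uses component-wise medians as centers — the exact
# minimizer of within-cluster L1 dispersion — so the assignment metric and
# the center update optimize the same objective.

#' ROI mask
#'
#' A per-spot boolean mask over a coordinate grid, either supplied as
#' reference (stand-in for H&E co-registration) or derived from a
#' segmentation by cluster matching.
#'
#' @param coords Data frame with `x`, `y` per spot.
#' @param mask Logical vector, one per spot, at least one `TRUE`.
#' @param source `"reference"` or `"cluster_match"`.
#' @return A list of class `roi_mask`.
#' @export
roi_mask <- function(coords, mask, source = c("reference", "cluster_match")) {
  source <- match.arg(source)
  mask <- as.logical(mask)
  if (length(mask) != nrow(coords)) stop_ovimsi("mask length != spot count")
  if (!any(mask)) stop_ovimsi("ROI mask must select at least one spot")
  structure(list(coords = as.data.frame(coords)[, c("x", "y")],
                 mask = mask, source = source),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask (%s): %d / %d spots\n", x$source, sum(x$mask),
              length(x$mask)))
  invisible(x)
}

#' Channel-level table for full-spectrum operations
#'
#' Wraps a dataset's raw channel matrix in the feature-table container so
#' that [bisecting_kmeans()] (and [average_peak_intensity()]) can operate on
#' the whole acquired spectrum instead of detected peak features — the
#' higher-fidelity, slower alternative to feature-level segmentation. Each
#' "peak" is a single channel.
#'
#' @param dataset A preprocessed `ion_image_dataset`.
#' @return A `feature_table` with one column per retained channel.
#' @export
channel_table <- function(dataset) {
  pk <- new_peak_set(
    data.frame(center = dataset$mz, lo = dataset$mz, hi = dataset$mz,
               coefficient = NA_real_),
    sigma = NA_real_, mode = dataset$mode, provenance = list(source = "channels"))
  structure(list(
    spots = data.frame(sample_id = dataset$sample_id, group = dataset$group,
                       timepoint = dataset$timepoint, mode = dataset$mode,
                       x = dataset$coords$x, y = dataset$coords$y),
    peaks = pk, values = dataset$intensities),
    class = "feature_table")
}

l1_dispersion <- function(X) {
  if (nrow(X) == 0) return(0)
  med <- apply(X, 2, stats::median)
  sum(abs(sweep(X, 2, med)))
}

l1_dist_to <- function(X, center) {
  rowSums(abs(sweep(X, 2, center)))
}

# one L1 2-means split; returns NULL when it cannot produce two nonempty,
# dispersion-reducing children
split_l1 <- function(X, restarts) {
  n <- nrow(X)
  best <- NULL
  init_pairs <- vector("list", restarts)
  # restart 1: deterministic farthest-pair seeding (data-dependent, hence
  # invariant to spot order); remaining restarts: random distinct rows
  med <- apply(X, 2, stats::median)
  i1 <- which.max(l1_dist_to(X, med))
  i2 <- which.max(l1_dist_to(X, X[i1, ]))
  init_pairs[[1]] <- c(i1, i2)
  for (r in seq_len(restarts - 1))
    init_pairs[[r + 1]] <- sample.int(n, 2)
  for (init in init_pairs) {
    c1 <- X[init[1], ]; c2 <- X[init[2], ]
    lab <- NULL
    for (it in 1:100) {
      d1 <- l1_dist_to(X, c1); d2 <- l1_dist_to(X, c2)
      new_lab <- ifelse(d1 <= d2, 1L, 2L)
      if (identical(new_lab, lab)) break
      lab <- new_lab
      if (all(lab == 1L) || all(lab == 2L)) break
      c1 <- apply(X[lab == 1L, , drop = FALSE], 2, stats::median)
      c2 <- apply(X[lab == 2L, , drop = FALSE], 2, stats::median)
    }
    if (all(lab == 1L) || all(lab == 2L)) next  # empty child, retry
    obj <- l1_dispersion(X[lab == 1L, , drop = FALSE]) +
      l1_dispersion(X[lab == 2L, , drop = FALSE])
    if (is.null(best) || obj < best$obj) best <- list(lab = lab, obj = obj)
  }
  best
}

#' Bisecting k-means segmentation (Manhattan metric)
#'
#' Starting from a single cluster, repeatedly splits the leaf with the
#' largest total Manhattan dispersion about its component-wise median into
#' two clusters by alternating L1 assignment / component-wise-median center
#' updates (best of `restarts` initializations; the first initialization is
#' a deterministic farthest-pair seeding, so results are invariant to spot
#' ordering on well-separated data). `depth` splits yield `depth + 1` leaf
#' clusters. Deterministic given `seed`.
#'
#' @param table A `feature_table` (typically TIC-normalized features).
#' @param depth Number of splits (>= 1); default 3. Per-split dispersions
#'   are reported in the tree so users can choose a depth from the
#'   diagnostics, mirroring an interactive depth choice.
#' @param seed Integer seed for the random restarts.
#' @param restarts Initializations per split.
#' @return A `segmentation_result`: `labels` (per-spot leaf ids), `tree`
#'   (one row per split: parent, children, dispersion before/after),
#'   `depth`, `seed`, and the spot table for alignment.
#' @export
bisecting_kmeans <- function(table, depth = 3L, seed = 1L, restarts = 5L) {
  X <- table$values
  n <- nrow(X)
  if (n == 0) stop_ovimsi("empty feature table")
  if (depth < 1) stop_ovimsi("depth must be >= 1")
  if (depth >= n) stop_ovimsi("depth must be smaller than the spot count")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  labels <- rep(1L, n)
  disp <- c(`1` = l1_dispersion(X))
  tree <- data.frame(parent = integer(), child1 = integer(),
                     child2 = integer(), dispersion_before = numeric(),
                     dispersion_after = numeric())
  next_id <- 2L
  for (s in seq_len(depth)) {
    splittable <- names(disp)[tabulate(labels)[as.integer(names(disp))] > 1 &
                                disp > 0]
    if (!length(splittable))
      stop_ovimsi("no divisible cluster left at split ", s,
                  " (clusters are single spots or have zero dispersion)")
    parent <- as.integer(splittable[which.max(disp[splittable])])
    rows <- which(labels == parent)
    res <- split_l1(X[rows, , drop = FALSE], restarts)
    if (is.null(res))
      stop_ovimsi("cluster ", parent, " could not be split into two ",
                  "nonempty clusters (identical spectra?)")
    if (res$obj >= disp[[as.character(parent)]])
      stop_ovimsi("split of cluster ", parent,
                  " does not reduce Manhattan dispersion")
    child2 <- next_id; next_id <- next_id + 1L
    labels[rows[res$lab == 2L]] <- child2
    d1 <- l1_dispersion(X[labels == parent, , drop = FALSE])
    d2 <- l1_dispersion(X[labels == child2, , drop = FALSE])
    tree <- rbind(tree, data.frame(
      parent = parent, child1 = parent, child2 = child2,
      dispersion_before = disp[[as.character(parent)]],
      dispersion_after = res$obj))
    disp[[as.character(parent)]] <- d1
    disp[[as.character(child2)]] <- d2
  }
  structure(list(labels = labels, tree = tree, depth = as.integer(depth),
                 seed = as.integer(seed), spots = table$spots),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: depth %d, %d leaves over %d spots\n",
              x$depth, length(unique(x$labels)), length(x$labels)))
  print(table(cluster = x$labels))
  invisible(x)
}

dice_coefficient <- function(a, b) {
  if (!any(a) && !any(b)) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Select the epithelium ROI from a segmentation
#'
#' Scores every leaf cluster by its Dice overlap with the reference mask and
#' returns the best-matching cluster (or, with `dice_threshold`, the union
#' of all clusters above the threshold) as the working ROI. This replaces
#' the manual co-registration step: the reference mask is an explicit input.
#'
#' @param seg A `segmentation_result`.
#' @param reference A [roi_mask()] (e.g., [reference_mask()] output).
#' @param dice_threshold Optional: take the union of clusters with Dice
#'   above this value instead of the single best cluster.
#' @return A [roi_mask()] with `source = "cluster_match"`; attribute
#'   `"dice"` holds the per-cluster Dice scores.
#' @export
select_roi <- function(seg, reference, dice_threshold = NULL) {
  ref_rows <- table_roi_rows(
    structure(list(spots = seg$spots), class = "feature_table"), reference)
  if (!any(ref_rows)) stop_ovimsi("reference mask is empty on this grid")
  leaves <- sort(unique(seg$labels))
  dice <- vapply(leaves, function(cl)
    dice_coefficient(seg$labels == cl, ref_rows), numeric(1))
  names(dice) <- leaves
  if (max(dice) < 0.2)
    stop_ovimsi("segmentation failed to isolate the epithelium ",
                "(best cluster Dice ", round(max(dice), 3), " < 0.2)")
  chosen <- if (is.null(dice_threshold)) leaves[which.max(dice)]
            else leaves[dice > dice_threshold]
  out <- roi_mask(seg$spots[, c("x", "y")], seg$labels %in% chosen,
                  source = "cluster_match")
  attr(out, "dice") <- dice
  attr(out, "clusters") <- chosen
  out
}

#' Ion density map for one peak
#'
#' Aggregated (summed) intensity of one peak interval per spot, arranged on
#' the coordinate grid.
#'
#' @param dataset An `ion_image_dataset`.
#' @param peak `c(lo, hi)` m/z interval, or a one-row slice of
#'   `peak_set$peaks` (its `lo`/`hi` are used).
#' @return Matrix (ny x nx) of per-spot values, `NA` off-grid, of class
#'   `ion_density_map`.
#' @export
ion_density_map <- function(dataset, peak) {
  if (is.data.frame(peak)) peak <- c(peak$lo[1], peak$hi[1])
  jj <- which(dataset$mz >= peak[1] & dataset$mz <= peak[2])
  if (!length(jj))
    stop_ovimsi("no channels in the requested m/z interval [", peak[1], ", ",
                peak[2], "] (excluded or outside the axis)")
  vals <- rowSums(dataset$intensities[, jj, drop = FALSE])
  nx <- max(dataset$coords$x) + 1L; ny <- max(dataset$coords$y) + 1L
  img <- matrix(NA_real_, ny, nx)
  img[cbind(dataset$coords$y + 1L, dataset$coords$x + 1L)] <- vals
  structure(img, class = c("ion_density_map", "matrix"),
            mz_interval = peak)
}

#' Plot an ion density map
#'
#' Renders the per-spot intensities with a blue-to-red gradient (blue low,
#' red high).
#'
#' @param x An `ion_density_map`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return The map, invisibly.
#' @export
plot.ion_density_map <- function(x, main = NULL, ...) {
  pal <- grDevices::colorRampPalette(
    c("blue", "cyan", "green", "yellow", "orange", "red"))(64)
  graphics::image(t(unclass(x)), col = pal, axes = FALSE,
                  main = main %||% sprintf("m/z %.1f-%.1f",
                                           attr(x, "mz_interval")[1],
                                           attr(x, "mz_interval")[2]), ...)
  invisible(x)
}
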