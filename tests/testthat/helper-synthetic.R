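# Shared fixtures: a compact synthetic study configuration small enough for
# unit tests (coarser axis, narrower range, fewer peaks than the full-study
# defaults) but with the same structure: ring geometry, both diet groups,
# planted DRLs in both directions, matrix artifact at m/z 500.

small_config <- function(...) {
  defaults <- list(
    grid = c(14L, 14L), mz_range = c(450, 1000), mz_step = 0.2,
    n_shared = 12L, n_epithelium = 4L, n_stroma = 4L, n_background = 2L,
    design = study_design(timepoints = "16w", modes = "positive"))
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

small_params <- function(...) preprocess_params(tophat_width = 15L, ...)

# run the small study through preprocessing and feature extraction
small_feature_table <- function(seed = 1, config = small_config(),
                                params = small_params()) {
  st <- generate_study(config, seed)
  prep <- lapply(st$datasets, preprocess_dataset, params = params)
  ms <- mean_spectrum(prep)
  msc <- tophat_baseline_correct(ms, params$tophat_width)
  attr(msc, "mz") <- attr(ms, "mz")
  pk <- omp_detect_peaks(msc, sigma = config$sigma_peak,
                         mode = config$design$modes[1])
  list(study = st, prep = prep, peaks = pk,
       table = extract_features(prep, pk))
}

# brute-force O(n^2) AUC oracle: pairwise comparison count with half credit
# for ties (independent of the rank-based implementation)
auc_pairwise <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# adjusted Rand index between two labelings (chance-corrected agreement),
# computed from the contingency table
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

dice_of <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# map a planted DRL direction onto the DM calling direction
DIR_MAP <- c(up_in_HFHS = "HFHS_vs_CTRL", down_in_HFHS = "CTRL_vs_HFHS")

# score detected DMs against the manifest: sensitivity, false-discovery
# proportion, and worst center error among recovered DRLs
score_dms <- function(dms, drls, tol = 0.2) {
  hit <- vapply(seq_len(nrow(drls)), function(i)
    any(abs(dms$center_mz - drls$mz[i]) <= tol &
          dms$direction == DIR_MAP[[drls$direction[i]]]), logical(1))
  fp <- if (nrow(dms)) vapply(seq_len(nrow(dms)), function(i)
    all(abs(dms$center_mz[i] - drls$mz) > tol), logical(1)) else logical(0)
  list(sensitivity = mean(hit), n_fp = sum(fp),
       fdp = if (nrow(dms)) mean(fp) else 0)
}
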