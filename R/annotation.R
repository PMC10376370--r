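# Putative lipid annotation by monoisotopic mass matching.
#
# The table is formula-derived: each species' elemental composition follows
# from its class head group plus the summed acyl composition (total carbons n,
# total double bonds d), and the monoisotopic mass is computed from standard
# atomic masses. Matching is mass-only ("putative"): MS/MS confirmation is
# out of scope, and ambiguous hits are reported as joined class categories
# ("PC/PE" style) rather than resolved.

# monoisotopic atomic masses (Da), most abundant isotope
ATOMIC_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                 O = 15.9949146196, P = 30.97376163)
PROTON_MASS <- 1.00727646688

# adduct mass shifts (Da) applied to the neutral species, per ionization mode
ADDUCTS <- list(
  positive = c("[M+H]+"  = PROTON_MASS,
               "[M+Na]+" = 22.98976928 - 0.00054858,
               "[M+K]+"  = 38.96370649 - 0.00054858),
  negative = c("[M-H]-"  = -PROTON_MASS))

LIPID_CLASSES <- c("PC", "PE", "PS", "PI", "SM", "LPC", "LPE", "LPS", "LPI")

# element counts as a function of total acyl carbons n and double bonds d;
# diacyl glycerophospholipids = head-group backbone + two acyl esters, lyso
# forms drop one acyl (−CnH(2n−2)O relative to the diacyl with the same n).
lipid_formula <- function(class, n, d) {
  switch(class,
    PC  = c(C = n + 8, H = 2 * n - 2 * d + 16, N = 1, O = 8,  P = 1),
    PE  = c(C = n + 5, H = 2 * n - 2 * d + 10, N = 1, O = 8,  P = 1),
    PS  = c(C = n + 6, H = 2 * n - 2 * d + 10, N = 1, O = 10, P = 1),
    PI  = c(C = n + 9, H = 2 * n - 2 * d + 15, N = 0, O = 13, P = 1),
    SM  = c(C = n + 5, H = 2 * n - 2 * d + 13, N = 2, O = 6,  P = 1),
    LPC = c(C = n + 8, H = 2 * n - 2 * d + 18, N = 1, O = 7,  P = 1),
    LPE = c(C = n + 5, H = 2 * n - 2 * d + 12, N = 1, O = 7,  P = 1),
    LPS = c(C = n + 6, H = 2 * n - 2 * d + 12, N = 1, O = 9,  P = 1),
    LPI = c(C = n + 9, H = 2 * n - 2 * d + 17, N = 0, O = 12, P = 1),
    stop_ovimsi("unknown lipid class: ", class))
}

formula_string <- function(counts) {
  parts <- vapply(names(counts), function(el) {
    k <- counts[[el]]
    if (k == 0) "" else if (k == 1) el else paste0(el, k)
  }, character(1))
  paste0(parts, collapse = "")
}

formula_mass <- function(counts) sum(counts * ATOMIC_MASS[names(counts)])

#' Build a formula-derived lipid mass table
#'
#' Enumerates phospholipid and sphingomyelin species over a grid of total
#' acyl carbons and double bonds and computes each monoisotopic mass from
#' standard atomic masses. Lyso (single-acyl) classes use their own, shorter
#' carbon range.
#'
#' @param classes Lipid classes to enumerate; any of
#'   `r paste(LIPID_CLASSES, collapse = ", ")`.
#' @param carbons Integer vector of total acyl carbon counts for diacyl
#'   classes and SM.
#' @param double_bonds Integer vector of total double-bond counts.
#' @param lyso_carbons,lyso_double_bonds Ranges for the lyso classes.
#' @return Data frame of class `lipid_db`: `lipid_class`, `carbons`,
#'   `double_bonds`, element counts, `formula`, `monoisotopic_mass` (Da).
#' @export
#' @examples
#' db <- build_lipid_db("PC", carbons = 34, double_bonds = 1)
#' db$formula            # "C42H82NO8P"
#' db$monoisotopic_mass  # 759.5778
build_lipid_db <- function(classes = LIPID_CLASSES,
                           carbons = 26:44, double_bonds = 0:6,
                           lyso_carbons = 14:22, lyso_double_bonds = 0:4) {
  bad <- setdiff(classes, LIPID_CLASSES)
  if (length(bad)) stop_ovimsi("unknown lipid class: ", paste(bad, collapse = ", "))
  if (!length(carbons) || !length(double_bonds))
    stop_ovimsi("empty carbon or double-bond range")
  rows <- list()
  for (cl in classes) {
    lyso <- startsWith(cl, "L")
    cs <- if (lyso) lyso_carbons else carbons
    ds <- if (lyso) lyso_double_bonds else double_bonds
    for (n in cs) for (d in ds) {
      if (d > n / 2) next
      cnt <- lipid_formula(cl, n, d)
      rows[[length(rows) + 1L]] <- data.frame(
        lipid_class = cl, carbons = n, double_bonds = d,
        C = cnt[["C"]], H = cnt[["H"]], N = cnt[["N"]],
        O = cnt[["O"]], P = cnt[["P"]],
        formula = formula_string(cnt),
        monoisotopic_mass = formula_mass(cnt))
    }
  }
  db <- do.call(rbind, rows)
  db <- db[order(db$monoisotopic_mass), , drop = FALSE]
  rownames(db) <- NULL
  class(db) <- c("lipid_db", "data.frame")
  db
}

#' Theoretical ion m/z values for a lipid table
#'
#' Expands a lipid table by the adduct set of one ionization mode
#' (positive: protonated, sodiated, potassiated; negative: deprotonated).
#'
#' @param db A `lipid_db`.
#' @param mode `"positive"` or `"negative"`.
#' @return Data frame with one row per species x adduct and a `theoretical_mz`
#'   column.
#' @export
lipid_ion_mz <- function(db, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  adds <- ADDUCTS[[mode]]
  out <- do.call(rbind, lapply(seq_along(adds), function(i) {
    d <- as.data.frame(db)
    d$adduct <- names(adds)[i]
    d$theoretical_mz <- d$monoisotopic_mass + adds[[i]]
    d
  }))
  rownames(out) <- NULL
  out
}

#' Putatively annotate one discriminative mass
#'
#' Matches a discriminative m/z against the species x adduct masses of its
#' ionization mode within a mass tolerance. All matches are kept: the
#' category string joins the sorted distinct classes of the candidates
#' ("PC/PE"), or is `"unassigned"` when nothing matches.
#'
#' @param dm A one-row data frame (or list) with `center_mz` and `mode`
#'   (e.g., one row of [detect_dms()] output).
#' @param db A `lipid_db` from [build_lipid_db()].
#' @param tolerance Mass tolerance in Da (default 0.05, TOF-scale).
#' @return A list of class `annotation_record`: `dm`, `candidates` (data
#'   frame: class, species composition, adduct, theoretical m/z, mass error),
#'   and `category`.
#' @export
annotate_dm <- function(dm, db, tolerance = 0.05) {
  if (tolerance <= 0) stop_ovimsi("tolerance must be positive")
  ions <- lipid_ion_mz(db, dm$mode)
  err <- ions$theoretical_mz - dm$center_mz
  hit <- abs(err) <= tolerance
  cand <- ions[hit, c("lipid_class", "carbons", "double_bonds", "formula",
                      "adduct", "theoretical_mz")]
  cand$mass_error <- err[hit]
  cand <- cand[order(abs(cand$mass_error)), , drop = FALSE]
  rownames(cand) <- NULL
  category <- if (nrow(cand) == 0) "unassigned" else
    paste(sort(unique(cand$lipid_class)), collapse = "/")
  structure(list(dm = dm, candidates = cand, category = category),
            class = "annotation_record")
}

#' @export
print.annotation_record <- function(x, ...) {
  cat(sprintf("m/z %.4f [%s]: %s (%d candidate%s)\n",
              x$dm$center_mz, x$dm$mode, x$category, nrow(x$candidates),
              if (nrow(x$candidates) == 1) "" else "s"))
  invisible(x)
}

#' Annotate a table of discriminative masses
#'
#' @param dms Data frame of discriminative masses ([detect_dms()] output).
#' @param db A `lipid_db`.
#' @param tolerance Mass tolerance in Da.
#' @return The input with `category` and `n_candidates` columns appended;
#'   the full `annotation_record` list is attached as attribute `"records"`.
#' @export
annotate_dms <- function(dms, db, tolerance = 0.05) {
  records <- lapply(seq_len(nrow(dms)), function(i)
    annotate_dm(dms[i, , drop = FALSE], db, tolerance))
  dms$category <- vapply(records, `[[`, character(1), "category")
  dms$n_candidates <- vapply(records, function(r) nrow(r$candidates), integer(1))
  attr(dms, "records") <- records
  dms
}

#' Count annotation categories per time point and direction
#'
#' @param annotated Output of [annotate_dms()] (needs `category`,
#'   `timepoint`, `direction` columns).
#' @return List with `counts` (category x timepoint x direction long data
#'   frame), `totals` (per category), and `fraction_annotated` (share of
#'   masses with at least one candidate).
#' @export
summarize_classes <- function(annotated) {
  if (nrow(annotated) == 0)
    return(list(counts = data.frame(category = character(), timepoint = character(),
                                    direction = character(), n = integer()),
                totals = data.frame(category = character(), n = integer()),
                fraction_annotated = NA_real_))
  counts <- as.data.frame(
    table(category = annotated$category, timepoint = annotated$timepoint,
          direction = annotated$direction),
    responseName = "n", stringsAsFactors = FALSE)
  counts <- counts[counts$n > 0, , drop = FALSE]
  rownames(counts) <- NULL
  totals <- as.data.frame(table(category = annotated$category),
                          responseName = "n", stringsAsFactors = FALSE)
  list(counts = counts, totals = totals,
       fraction_annotated = mean(annotated$category != "unassigned"))
}
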