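---
title: "Methods: diet-discriminative lipid detection in oviductal MALDI-MSI data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet-discriminative lipid detection in oviductal MALDI-MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

MALDI mass spectrometry imaging (MSI) of oviduct cross-sections yields one
mass spectrum per raster spot over an m/z 400–2000 window. The biological
question is which lipid ions distinguish the oviductal epithelium (OE) of
animals on an obesogenic high-fat/high-sugar (HFHS) diet from controls, at
each feeding time point, in each ionization mode. Answering it requires a
chain of standard MSI operations — baseline correction, normalization, peak
detection, spatial segmentation to isolate the epithelial cell layer, then a
per-peak two-group comparison — and `oviMSI` implements that chain end to
end, together with a ground-truth simulator that makes every stage testable
without instrument data.

The pipeline operates per *batch*: all control and HFHS sections of one
(time point, mode) combination are preprocessed, peak-picked, and analyzed
together, mirroring how sections are acquired and processed together in
practice. Absolute intensities are not comparable across batches; only
within-batch group contrasts are interpreted.

## Preprocessing

Order is fixed as **mass filters → Tophat → TIC normalization** and enforced
by `preprocess_dataset()` rather than left to callers, because the total ion
count depends on which channels are retained: excluding the matrix-cluster
window *after* normalization would let matrix signal distort every spot's
scale factor.

* **Mass filters.** Channels below m/z 400 are dropped (the instrument's
  low-mass deflection), and exclusion windows are removed. The default
  window is [493, 507]: the matrix-cluster interval of total width 14
  centered at m/z 500. Centering is an interpretation — the interval is
  described by its location and size only — and is documented here as such.
* **Tophat baseline correction.** Each spectrum minus its morphological
  opening (flat structuring element). The width default of 29 channels is
  roughly five times the synthetic peak FWHM at the default 0.1 Th spacing:
  wide enough that isolated peaks pass through unchanged (the opening of a
  peak narrower than the element on a flat background is the background),
  narrow enough to track slow drift. Width is in channels, odd, exposed in
  the configuration.
* **TIC normalization.** Each spot is scaled so its channel sum is 1
  (`unit_sum`, default) or the pre-normalization mean TIC (`mean_tic`).
  Zero-TIC spots cannot be normalized and are dropped with a warning, never
  imputed.

One consequence of unit-sum normalization worth stating plainly: it is
*compositional*. If a planted (or real) regulation raises the total signal
of one group's epithelium, every unregulated peak in that group is scaled
down slightly, which biases per-peak comparisons toward the opposite
direction. With many peaks sharing the TIC the effect is second-order; in
deliberately tiny configurations (as in some unit tests) it can produce a
borderline false call. This is a property of TIC normalization itself, not
of the implementation.

## Peak detection: orthogonal matching pursuit with centroid alignment

Peaks are detected once per batch, on the pooled mean spectrum of all the
batch's sections. Because averaging zero-clipped noise leaves a small
positive pedestal, the mean spectrum is Tophat-corrected with the same
element width before peak picking.

The detector is orthogonal matching pursuit (OMP) over a dictionary of
unit-norm Gaussian atoms, one centered at every channel, with width `sigma`
(the expected peak width; for synthetic data, the generator's own peak
sigma). Each iteration selects the atom with the largest positive inner
product with the residual, refits all selected coefficients by least squares
(incremental Cholesky on the analytically known Gram matrix), and updates
the residual, whose norm is non-increasing by construction. Iteration stops
at whichever comes first:

* relative residual norm ≤ `residual_tol` (default 0.02);
* `max_peaks` atoms selected (default 500);
* the best remaining atom correlation falls below `snr_min` (default 3)
  times the robust noise level, estimated as median + MAD of the atom
  correlations. This signal-to-noise gate — standard practice in spectral
  peak pickers — is what actually terminates the search on noisy data;
  without it the residual criterion forces the fit of hundreds of noise
  bumps, since off-peak noise can hold a few percent of the spectrum norm.
  On noise-free spectra median and MAD are both zero and the gate is
  inactive.

Two post-processing steps matter for mass accuracy. First, atoms closer
than 3σ are consolidated into one peak at their coefficient-weighted mean
position: a peak whose true center falls between two channels is otherwise
represented by a pair of adjacent atoms. Second, each center is aligned to
the mean spectrum by centroid matching — the intensity-weighted centroid in
a ±2σ window — giving sub-channel accuracy (in practice ≲0.01 Th at 0.1 Th
spacing), which the 0.05 Da annotation tolerance depends on. Peak intervals
are `center ± 3σ`, truncated at midpoints between neighbors so they never
overlap.

Per-spot feature extraction then locates the local maximum in each interval,
accepts the peak if its local centroid lies inside the interval, and records
the summed interval intensity (aggregation by sum, not maximum — a
configurable, documented choice). Skyline spectra (per-channel maxima over a
group's spots) serve for overview plots; `average_peak_intensity()` gives
the single-number ROI intensity summary compared between groups.

## Spatial segmentation and ROI selection

Segmentation is bisecting k-means under the Manhattan (L1) metric: starting
from one cluster, the leaf with the largest total L1 dispersion about its
component-wise median is split into two by alternating L1 assignment and
component-wise-median center updates. Medians, not means, are used as
centers because the component-wise median minimizes L1 dispersion — the
assignment metric and the center update then optimize the same objective.
The first initialization of every split is a deterministic farthest-pair
seeding (which makes results invariant to spot ordering on separable data);
the remaining restarts are random. Each split must strictly reduce
dispersion.

Segmentation runs per section on the TIC-normalized feature table (spots ×
peaks) rather than on all ~16,000 raw channels — a tractability choice; the
feature table carries the same regional contrast. The clustering depth that
a human would choose interactively is a configuration integer (default 3),
and the per-split dispersion tree is reported so users can revise the choice
from diagnostics. The planted three-region geometry (epithelium ring,
stroma, off-tissue background) is recovered at depth 2.

Manual co-registration with stained optical images is replaced by an
explicit reference mask input: `select_roi()` scores every leaf cluster by
its Dice overlap with the mask and returns the best cluster (optionally the
union above a Dice threshold). A best Dice below 0.2 is treated as a failed
segmentation and raises an error rather than returning a wrong ROI.

## Bidirectional ROC analysis

For each peak, ROI spot intensities are pooled across the sections of each
group and the area under the ROC curve for HFHS vs. CTRL is computed by the
rank formula (ties half-credited, the Mann–Whitney convention — the tie rule
is a choice documented here). A peak is called a discriminative mass (DM) in
the HFHS_vs_CTRL direction if AUC ≥ 0.7, and in the CTRL_vs_HFHS direction
if 1 − AUC ≥ 0.7; testing both directions avoids biasing detection toward
abundant ions. Above threshold 0.5 the directions are mutually exclusive,
and calling is monotone in the threshold.

Two caveats are inherited deliberately from the source analysis and
documented prominently rather than "fixed":

* **Pseudoreplication.** Spots (spectra), not animals, are the observations
  entering the ROC; with 3 sections per group the effective sample size is
  far smaller than the spot count suggests. A conservative alternative that
  first averages spots within each section (`by_sample_mean = TRUE`) is
  provided, but with 3 vs 3 sections the AUC granularity (ninths) makes a
  0.7 threshold nearly vacuous, which is presumably why the original
  analysis pooled spectra.
* **No multiple-testing correction.** Calling is by the AUC threshold
  alone.

Cross-time-point persistence is assessed by `overlap_dms()`: greedy
nearest-first one-to-one matching of DM centers within 0.1 Th (a default
chosen at the scale of the axis spacing), same ionization mode only.

## Putative annotation

The lipid table is formula-derived: for each class (PC, PE, PS, PI, SM and
their lyso forms), the elemental composition follows from the class head
group plus the summed acyl composition (total carbons n, total double bonds
d), and the monoisotopic mass is computed from standard atomic masses. A DM
is matched against species × adduct masses of its ionization mode
(positive: +H, +Na, +K; negative: −H) within 0.05 Da (TOF-scale, configurable).
All matches are kept, and the category string joins the sorted distinct
candidate classes ("PC/PE"), or reads "unassigned". Annotation is mass-only
and therefore *putative* — MS/MS confirmation is outside this package's
scope — and masses in the 1400–1600 region remain unassigned by the default
table, which contains no species there.

## The synthetic study and what it does (not) establish

`generate_study()` builds the testbed: a spot grid with an epithelium ring
around a lumen, surrounding stroma, and off-tissue background; per-mode peak
sets drawn mostly from the packaged lipid ion masses (a configurable
fraction at random unassignable m/z), placed preferentially in 700–900 Th
with a minor 1400–1600 component and a minimum separation of 6σ; per-region
affinity weights; differentially regulated lipids (DRLs) planted in both
directions by scaling epithelial amplitudes of the HFHS group by the fold
change; a smooth positive random baseline per section; lognormal per-spot
TIC multipliers; a lognormal per-section intensity scalar; additive Gaussian
channel noise truncated at zero; and a matrix-cluster artifact at m/z 500
for the exclusion window to remove. Everything is recorded in a manifest,
and generation is bit-reproducible given (config, seed).

Defaults and the reasoning behind them:

* grid 18×18 (≈44 epithelium spots per section); axis 400–2000 Th at 0.1 Th;
  peak σ 0.25 Th; 30 shared + 10 epithelial + 10 stromal + 2 background
  peaks; 3 sections per group; fold change 2.5, four DRLs up and four down;
  TIC log-sd 0.15; section jitter log-sd 0.05; baseline amplitude 20% of
  the base peak height, varying over ~40 Th.
* The per-section jitter is a single scalar: it models section-to-section
  matrix-deposition and detector differences, which is precisely the
  variation TIC normalization exists to remove. Making it per-peak would
  model biological replicate variation instead; that is deliberately out of
  this generator's scope, and the pseudoreplication caveat above is the
  honest statement of what pooling then means.
* Channel noise sigma defaults to 5 (5% of the base peak amplitude). This
  must stay well below the baseline: the truncated-additive noise model
  interacts with morphology — when the noise scale reaches the baseline
  scale, zero-clipping pins the morphological opening to the noise floor
  and Tophat can no longer remove the baseline, whose per-section leftovers
  then masquerade as group structure. At 5% the baseline is essentially
  fully removed and the model behaves like the shot-to-shot variability of
  well-accumulated TOF pixel spectra (hundreds of laser shots per raster
  position).
* "Zero noise" in null-calibration checks means every stochastic nuisance
  off — channel noise, TIC variation, section jitter, *and* the per-section
  baseline — since a deterministic baseline difference between sections
  produces deterministic orderings that a rank statistic reads as signal.

Passing recovery tests on this generator shows the chain of methods is
implemented correctly and is calibrated under the stated model. It does
*not* show the method would perform equally on real tissue: the generator
has no isotope envelopes, no mass-resolution dependence on m/z, no count
statistics, no spatial autocorrelation of noise, and biological
between-animal variation is reduced to a scalar. These omissions are
intentional scope.

## Numerical choices and degenerate inputs

* Morphological erosion/dilation use shrunken windows at the spectrum edges
  (no padding), so edge channels are compared against in-range values only.
* OMP refuses to select an atom twice, skips near-collinear atoms
  (Cholesky diagonal ≤ 1e−10), discards atoms whose refit coefficient is
  not positive, and verifies residual monotonicity at every step.
* An all-zero spectrum yields an empty peak set; identical rows make a
  cluster unsplittable and raise an error; an empty child in a 2-means
  split triggers a fresh restart, then an error when restarts are
  exhausted.
* ROI masks must select at least one spot; an ROI empty for any section
  aborts DM detection with the section named.
* Ties in L1 assignment go to the first center; ties in the AUC receive
  half credit.

## Problem sizes used by the packaged checks

The test suite exercises most operations on a compact configuration
(14×14 grid, 450–1000 Th at 0.2 Th, ~23 peaks) and the end-to-end recovery
checks on the full default configuration restricted to the unit the
pipeline actually processes at a time — one batch (one time point, one
mode, 3 sections per group, both groups) — across five seeds. Multi-batch
orchestration (several time points and modes, cross-time-point overlap) is
exercised on the compact configuration. These sizes are the package's
choice of test scale; all of them are configuration values, and nothing in
the implementation depends on them.
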