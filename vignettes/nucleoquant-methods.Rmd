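---
title: "Methods: nucleolar morphometry, aggregation scoring and polysome quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleolar morphometry, aggregation scoring and polysome quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoquant)
```

nucleoquant quantifies three readouts that together describe a cell's
proteostasis state: nucleolar size and activity (ribosome biogenesis),
polyglutamine-EGFP aggregation (protein folding load), and polysome
profiles (translational engagement). This vignette is the package's own
account of the models and the choices behind them; every number it
mentions is computed by the test suite or by `scripts/acceptance.R`, not
asserted here.

## Nucleolar morphometry

### Model

A two-channel micrograph carries a DNA stain and a nucleolar marker
(nucleolin/fibrillarin immunofluorescence, a GFP fusion, or FUrd labeling
of nascent rRNA). The pipeline is:

1. **Nuclei** (`segment_nuclei()`): global Otsu threshold on the DNA
   channel, hole filling, 4-connected labeling, removal of objects below
   `min_area_px` (default 80 px) and of objects touching the image border
   (the usual convention — truncated nuclei bias area and intensity
   statistics; disable with `exclude_border = FALSE`).
2. **Nucleoli** (`segment_nucleoli()`): a *per-nucleus* Otsu threshold on
   the marker channel. Thresholding per nucleus rather than globally makes
   nucleolus calls robust to between-cell differences in expression or
   staining; a nucleus whose bright class is not at least `min_enrichment`
   (default 1.2) times its dim class is treated as containing no nucleolar
   signal, which prevents Otsu from splitting pure noise in nucleoli-free
   nuclei. Pixels outside every nucleus are discarded. Fragments whose
   boundary gap is at most `merge_distance_px` (default 2 px) are merged
   into one object: both fragments are dilated by a disc of radius
   `ceiling(m/2)` and the dilated union is relabeled, which closes gaps of
   exactly ≤ m for even m (odd m over-merges by one pixel — if that
   matters, use the next even value). Each final object is assigned the
   nucleus containing its centroid; objects whose centroid falls in no
   nucleus are dropped.
3. **Measurement** (`measure_nuclei()`): per nucleus — nucleolus count,
   union nucleolar area, `size_fold` = nucleolar/nuclear area, mean,
   median and integrated marker intensity over nucleolar pixels, mean over
   the nucleoplasm (nuclear pixels minus nucleolar pixels, an exact
   partition), and the presence ratio = nucleolar mean / nucleoplasmic
   mean. The ratio is undefined (`NA`) when a nucleus has no nucleoli or
   no nucleoplasm. `measure_nascent_rna()` applies the same geometry to a
   FUrd channel; both the integrated and the median statistic are emitted,
   since either can serve as the transcription readout.

Manual curation of badly segmented cells is replaced by an automatic
`qc_pass` flag: solidity ≥ 0.8 and nuclear area at most twice the 99th
percentile of the field. Manual exclusion is not reproducible; a
deterministic flag is.

Worm intestinal nucleoli (a single-channel use case) are handled by the
same core with the marker channel doubling as the segmentation channel.

### Units and conventions

Coordinates are (row, column), 1-based; areas are pixel counts
(micrometre-squared only when `pixel_size_um` is supplied). Presence ratio
and size fold are dimensionless and invariant to any positive rescaling of
the marker channel; integrated intensities scale linearly with it.

## PolyQ aggregation scoring

### Model

Diffuse polyQ-EGFP fills the cell almost uniformly; aggregated polyQ
concentrates into bright foci beside dimmer cytoplasm. Two independent
quantifications are computed per cell:

* **Co-occurrence contrast** (`glcm_contrast()`): intensities are min–max
  quantized per cell to `gray_levels` bins (default 64), a symmetric
  normalized co-occurrence matrix is accumulated over in-cell pixel pairs
  at `offset_distance_px` (default 1) for each direction in
  {0°, 45°, 90°, 135°}, and the Haralick contrast
  `sum (i-j)^2 P(i,j)` is averaged over directions. A uniform cell scores
  exactly 0; a one-pixel checkerboard of the lowest and highest bins
  scores `(L-1)^2`. Per-cell quantization makes the statistic invariant
  under any increasing affine rescaling of one cell's intensities — and
  has a known flip side: in a cell with *no* structure, the min–max window
  collapses onto the noise, which is then amplified to the full gray
  range, so noisy diffuse cells score well above zero. Orderings within an
  experiment (diffuse vs. aggregated at matched noise) are meaningful;
  absolute contrast values across imaging settings are not. The
  monotonicity of contrast in the planted focus count is therefore
  established on noiseless scenes.
* **Focus counting** (`detect_foci()`): candidates are local maxima of the
  scale-normalized Laplacian-of-Gaussian response over radii
  `focus_scale_px` (default 2–5 px, four log-spaced scales), restricted to
  pixels where the candidate dominates adjacent scales. A candidate is
  retained when its Gaussian-smoothed peak intensity exceeds the cell
  median by at least `min_prominence` (default 0.3) times the in-cell
  intensity range; smoothing at the detection scale suppresses raw-noise
  maxima while retaining most of a true focus's amplitude. Overlapping
  detections are greedily deduplicated, strongest first. Counts map to the
  aggregation scale as S0 = 0 foci, S1 = 1–5, S2 = > 5 (`score_cells()`).
  The published rule also allows a texture-based call ("smooth / medium /
  rough"); no printed thresholds exist for it, so the count rule is the
  default and texture tertiles are left to the analyst via
  `texture_distribution()`.

Cells are grown from nuclear seeds by `segment_cells()`: seeded
propagation (intensity-regularized Voronoi growth, `lambda` = 0.05 as in
the common secondary-object default) into the region above a global Otsu
threshold computed on `log1p` intensities. The log transform matters: a
few very bright aggregate pixels otherwise pull the raw-domain Otsu
threshold above the diffuse cytoplasmic level and every "cell" collapses
to its nucleus. When nothing exceeds the threshold each cell falls back to
its nucleus footprint. EGFP-negative cells can be excluded from scoring
via `min_egfp` in `measure_cells()`.

## Polysome profiles

### Model

An OD260 trace along a sucrose gradient resolves the 40S and 60S subunits,
the 80S monosome and the polysome series. To compare samples loaded with
different amounts of material, each trace is normalized per sample:

1. Peaks are detected on a centered moving-average smoothed copy (window =
   2% of the trace length, forced odd — raw spectrometer noise makes a
   pointwise argmin ill-posed; the window is exposed as
   `smoothing_window`). The monosome is the tallest peak: the 80S peak
   dominates gradient profiles, and no other identifier is available in a
   raw trace.
2. The anchor X = 0 is the minimum of the smoothed signal between the peak
   preceding the monosome (60S) and the monosome; the second anchor is the
   minimum between the monosome and the next peak (the disome). Plateau
   minima take the leftmost index. Anchor indices refer to the raw trace.
3. Y is min–max normalized over the full sample (min → 0, max → 1); X is
   affinely mapped so the first anchor is 0 and the last datapoint 100.
   Points left of X = 0 (the 40S/60S region) enter no fraction.
4. The monosome fraction is the *sum* of normalized Y from X = 0 through
   the mono/disome valley; the polysome fraction is the sum from just
   after the valley to X = 100; the boundary sample belongs to the
   monosome window only (a `boundary` flag flips it; totals are conserved
   either way). Sum-based integration is area-proportional only on a
   uniform grid, so the loader warns on non-uniform spacing and offers
   linear resampling, and a trapezoid variant exists for non-uniform data.
   The readout is the polysome/monosome ratio.

The ratio is invariant, to machine precision, under affine transforms of
either axis of the raw trace: Y-normalization absorbs `a*y + b`, and the
anchors and windows are index-based so any monotone affine X rescaling
leaves the sums unchanged.

Window sums necessarily mix peak tails: the 80S tail past the mono/di
valley is counted as polysome, and the disome tail before it as monosome.
On well-resolved synthetic profiles the resulting bias stays within a few
percent; it grows toward ~10% when the polysome region is heavy and broad
(true ratio ≈ 4 in the acceptance sweep). This is a property of the
windowed-sum definition itself, not of its implementation.

## Synthetic data: what it emulates, what it does not

The generators render the statistical structure the analysis assumes, with
exact ground truth:

* `gen_nucleolar_scene()`: non-overlapping nuclear disks away from the
  border, each containing 0–6 nucleolar disks at a controlled
  marker-enrichment ratio over the nucleoplasm (default 3), plus additive
  Gaussian noise clipped at zero (default sd 2 = 5% of the nucleoplasm
  level of 40). Disks are rasterized hard-edged (a pixel belongs to a disk
  iff its center does) so every truth area is an exact pixel count and the
  noiseless enrichment ratio is exact by construction; anti-aliasing would
  trade that exactness for cosmetic realism. Sibling nucleoli keep a
  guaranteed *pixel* gap of `nucleolus_gap_px` (default 3) — the placement
  constraint carries a 1-px margin because a continuous gap of width g
  only guarantees g−1 empty pixel centers after rasterization. When a
  radius draw cannot be packed into a nucleus the radii shrink 10% per
  round (bounded), mirroring the smaller nucleoli of crowded nuclei.
* `gen_aggregation_scene()`: cells as disks with concentric nuclei; each
  cell carries exactly `total_signal_per_cell` EGFP (default 20,000)
  regardless of its focus count — cells with k > 0 foci concentrate
  `focus_intensity_share` (default 0.5) of it into k equal disks of radius
  `focus_radius_px` (default 3) and spread the rest uniformly. Signal
  conservation is exact before noise, so texture and focus-count effects
  are measured at fixed expression.
* `gen_polysome_trace()`: baseline plus area-parameterized Gaussian
  components (40S, 60S, 80S, disome, …) on a uniform grid; an
  exponentially modified Gaussian option emulates tailing. Component areas
  are the analytic truth: monosome truth is the 80S area, polysome truth
  the summed areas beyond it. `peaks_with_ratio()` retargets the
  polysome/monosome truth ratio by scaling polysome areas, splitting the
  factor between amplitude and width so a heavy polysome region broadens —
  as loaded gradients do — instead of outgrowing the 80S peak that anchor
  detection relies on.

Defaults are fixed once as realistic desk-scale conditions and are the
conditions under which the acceptance properties are stated. Not emulated:
point-spread-function optics, Poisson (shot) noise, photobleaching, 3-D
stacks, irregular cell shapes, multinucleated cells, gradient drift or
baseline slope. Passing tests therefore demonstrate that the algorithms
recover known truth under their stated assumptions — not that any specific
microscope's images will satisfy those assumptions.

All generators are bit-reproducible for a fixed spec and seed, and restore
the caller's RNG state.

## Numerical choices and degenerate inputs

* Otsu thresholds are computed on a 256-bin histogram; a constant input
  returns its own value, so nothing is ever segmented from a flat image.
* Labels are numbered 1..N in raster (row-major) order of each object's
  first pixel, making outputs stable across runs.
* Zero-intensity-range objects have contrast 0; objects with fewer than
  one valid pixel pair raise a `degenerate_object` error.
* A constant trace raises `degenerate_trace`; a monotone inter-peak
  segment raises `no_valley`; fewer than three detectable peaks raises
  `too_few_peaks`.
* Fraction windows need at least two samples each (`empty_window`
  otherwise); a non-positive monosome sum is an error rather than an
  infinite ratio.
* Refold capacity (recovered / non-shocked luciferase activity, computed
  within genotype) allows values above 1 with a warning and refuses a
  non-positive denominator.

## Problem sizes

The test suite and the acceptance script validate at desk scale: 512×512
fields with 25 nuclei (4 fields, 100 nuclei) for morphometry recovery,
55 cells across 5 fields for the contrast–focus-count relation, 200 cells
across 10 fields for S0/S1/S2 agreement, and 80 traces (4 true ratios ×
20 seeds, 600 samples each) for ratio recovery — sizes chosen so the full
suite runs in about a minute on one CPU while every recovery statistic
still has a meaningful denominator.

## Known limitations

* Per-object min–max quantization makes contrast values incomparable
  across noise levels; only orderings under matched conditions are
  interpretable (see above).
* The monosome-as-tallest-peak rule fails on profiles where a polysome
  peak genuinely dominates the 80S peak (heavy polysome loading with a
  collapsed monosome); such profiles need a manually supplied anchor.
* Segmentation is 2-D, threshold-based and shape-agnostic; densely
  touching nuclei are not split (no watershed declumping), matching the
  generator's non-touching scenes but not crowded tissue.
* The S1/S2 texture fallback ("medium/rough") is not automated — no
  printed thresholds exist — so scoring is purely count-based by default.
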