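---
title: "Measuring mineral apposition rate from double-label images: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mineral apposition rate from double-label images: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Dynamic bone histomorphometry estimates how fast new bone mineral is laid
down. Two fluorochromes are injected a known number of days apart — here
alizarin complexone (red) eight days before sacrifice and calcein green one
day before, a 7-day inter-label interval. Each dye binds to the mineralizing
front active on its injection day, so an undecalcified section shows two
roughly parallel fluorescent bands wherever bone grew between the
injections. The mineral apposition rate (MAR) is the distance between the
two band centerlines divided by the interval:

$$\mathrm{MAR} \;=\; \frac{\text{inter-label distance } (\mu m)}{\text{interval (days)} \times 1000} \quad \text{mm/day}.$$

Manual measurement draws a handful of perpendicular calipers per field.
`histomar` replaces that with a dense, automated estimate along the entire
labeled surface, plus the region-of-interest (ROI) aggregation and study
statistics used to analyze a multi-group, multi-timepoint animal study.

## Pipeline

`run_mar_pipeline()` chains six stages; every stage is exported and usable
on its own.

1. **Normalization** (`normalize_channels`). Each channel is rescaled so the
   1st percentile maps to 0 and the 99.9th to 1, then clipped. Percentiles
   use type-1 (order-statistic) quantiles, which makes re-normalizing an
   already-normalized image an exact no-op: the clipped mass at 0 and 1
   contains its own percentile. The saturation anchor is 99.9 rather than a
   more usual 99 because the labels are thin curves: in a realistic field of
   view they occupy a few percent of the pixels, and a 99th-percentile
   anchor can land *inside* the noise tail of the background, compressing
   the label/background contrast that the threshold step depends on.
2. **Channel separation** (`separate_channels`). Optional linear unmixing
   (alizarin = R − αG, calcein = G − βR, floored at zero) for RGB inputs
   with spectral crosstalk; the default α = β = 0 is a pass-through for
   pre-split two-channel images.
3. **Thresholding** (`threshold_mask`). Otsu's method by default, a fixed
   cutoff as fallback. Otsu assumes a bimodal histogram; this holds when
   the labeled bands are a non-negligible fraction of the field, which is
   why the synthetic validation images frame the labeled surface in a
   narrow strip rather than embedding two thin lines in a mostly empty
   square.
4. **Mask cleanup** (`clean_mask`). Morphological closing then opening with
   a disc of `smooth_radius_um`, hole filling gated by `max_hole_area_um2`
   (default `Inf` — by default no hole is "too big to be real", and setting
   every parameter to zero makes the function an exact identity), removal of
   components below `min_area_um2` (default 100), and removal of components
   whose *skeleton length* is below `min_length_um` (default 50): a label is
   an elongated structure, so short blobs are debris regardless of area.
5. **Skeletonization** (`skeletonize_pruned`). Zhang–Suen medial-axis
   thinning (hand-written; no installed R package offers binary thinning),
   followed by iterative spur pruning: endpoint-to-junction branches shorter
   than `prune_length_um` (default 30) are deleted and the result re-thinned
   until stable. Branch length counts diagonal steps as √2.
6. **Matching and quantification** (`match_skeletons`,
   `build_growth_field`, `compute_mar`). Each alizarin axis pixel is matched
   to its nearest calcein axis pixel; pairs farther apart than
   `max_distance_um` (default 100 µm — growth beyond ~14 µm/day over 7 days
   is not biologically plausible, so a longer match is a mismatch, not
   growth) are discarded. Matched segments are rasterized into a *growth
   mask*, the ribbon of tissue laid down between the injections. The
   distance field is read off this mask: a Euclidean distance transform
   (EDT), evaluated along the ribbon's own medial axis, gives the local
   half-width, i.e. half the inter-label distance.

### Numerical choices in the growth field

Several sub-pixel and topological details matter at the 10% accuracy level
and are worth stating explicitly.

* **EDT-to-distance conversion: `2·EDT − 1.5` pixels.** The EDT measures
  from the axis pixel *center* to the nearest *background* pixel center,
  i.e. 0.5 px beyond the mask boundary on each side; and the rasterized
  ribbon spans from the alizarin axis pixel to the calcein axis pixel
  *inclusive*, so its pixel extent is (separation + 1). Doubling the EDT
  and subtracting 1.5 px cancels both effects, making the estimator
  unbiased to within the ±0.5 px rasterization jitter.
* **Closing radius `max_distance_um / 4`.** Label dropout punches gaps in
  the ribbon; closing at a quarter of the matching cap seals gaps well
  below the cap scale while never merging surfaces the cap itself would not
  have matched.
* **8-connected components.** `EBImage::bwlabel` is 4-connected and splits
  an 8-connected skeleton at every diagonal step; `histomar` labels the
  3×3-dilated skeleton and restricts back to the foreground (`label8`),
  giving true 8-connected curve components.
* **Spur pruning at full-width scale (`2·maxEDT + 2` px).** Rasterization
  raggedness grows spurs on the ribbon skeleton as long as the ribbon's
  half-width, so half-width pruning is insufficient; full-width pruning
  removes them without shortening the true axis.
* **End-effect exclusion.** Near a ribbon terminus the EDT measures the
  distance to the *end cap*, not to the label surfaces. Axis pixels whose
  geodesic distance to the nearest skeleton endpoint is smaller than their
  own EDT are excluded. Regions too short to retain any pixel under this
  rule fall back to their maximum-EDT pixel and are flagged `degenerate`;
  an extreme case is a field built from a single matched pair, whose
  one-segment ribbon is everywhere 1 px wide and yields a pixel-scale
  distance — such fields are flagged rather than trusted.

ROIs are simple polygons named `H1, H2` (host bone), `C1, C2` (callus),
`J1, J2` (graft–host junction), `A1, A2` (allograft). `clip_field_to_roi`
keeps axis pixels inside or on the polygon boundary; `mar_by_roi` and
`summarize_by_region` aggregate per ROI and per region class with exact
pixel-weighted pooling of means and standard deviations.

## Synthetic data generator

Validation needs images whose true MAR is known exactly, so the generator
is first-class, tested code, not a fixture.

`generate_double_label_image` renders two bands whose medial axes are a
specified distance apart everywhere: horizontal parallel lines, or
concentric arcs (center placed below the image) when `curvature > 0`, which
keeps the axis separation constant along the curve. Degradations:

* **Label dropout** (`gap_fraction`, `gap_run_um`). Runs of physical length
  `gap_run_um` (default 50 µm — dropout in real sections affects surface
  patches of tens of micrometres, not isolated pixels) are erased along the
  band axis. The *same* runs are erased from both dyes: dropout models a
  quiescent or damaged surface patch, and such a patch binds neither label.
  This choice is also what keeps heavy dropout measurable — independent
  per-dye erasure creates diagonal matches across gap boundaries that are
  artifacts of the distance cap rather than growth. Blocks are chosen in
  random order and the prefix closest to the requested pixel fraction is
  erased, so the realized fraction is exact to half a block.
* **Noise** (`noise_sd`): additive Gaussian intensity noise, clipped to
  [0, 1].
* **Two RNG streams** (seed for dropout, seed + 1 for noise) so that
  changing `gap_fraction` alone leaves the noise field bit-identical —
  useful for differential tests.

What the generator does **not** emulate: intensity gradients across the
field, autofluorescence structure, out-of-plane blur, and label *thickness*
variation. Those affect segmentation difficulty, not the geometry the
distance estimator is validated on.

`generate_study_table` draws per-subject values from specified cell means
and standard deviations for a 3-group × 3-timepoint repeated-measures
design; `canine_callus_volume_params()` and `canine_torsion_params()`
carry the published cell statistics. When `truncate_at_zero = TRUE`
(default) negative draws are redrawn, which is the right support for
volumes but inflates the realized mean by σφ(z)/Φ(z) — about +4% for a
cell with mean ≈ 1.8 σ; mean-tracking checks therefore run with truncation
off.

`generate_torsion_curve` builds a torque–twist curve: linear loading at the
specified rigidity up to the yield torque, then a quadratic softening
segment whose tangent drops to a configurable fraction (default 0.5) of the
rigidity *at* the yield point, a peak at the ultimate torque, then a linear
drop. The deliberate slope knee at yield is the physical signature the
offset-yield rule detects; a slope-continuous transition would make any
offset rule overshoot the true yield by ~9% and is not how real
elastic-plastic transitions look at this scale. `extract_torsion_metrics`
recovers rigidity as the steepest slope over a contiguous 20% window of the
samples, yield by a 0.2%-of-peak-rotation offset line, ultimate torque as
the maximum, and work to failure by trapezoidal integration; monotone
curves that never drop are flagged `no_failure`.

## Statistics

* **ICC(2,1)** (`icc_two_way`): two-way random-effects, absolute-agreement,
  single-rater intraclass correlation, computed from the two-way mean
  squares with the F-based confidence interval of McGraw & Wong. Zero
  between-item variance returns 0 with a warning rather than a negative
  estimate.
* **Repeated-measures ANOVA** (`rm_anova_tukey`): `aov` with an
  `Error(subject_id)` stratum; group is tested against the between-subject
  error, time and group×time against the within error. Timepoints at which
  every observation is a structural zero (e.g. no callus exists yet at
  week 2) are dropped by default with a message — a constant column carries
  no information and breaks the variance decomposition. Per-timepoint group
  comparisons use Tukey's HSD at that timepoint.
* **One-way ANOVA + Tukey**, **Pearson/Spearman correlation**
  (`cor.test`), and **fold changes** reported rounded to one decimal with
  the unrounded ratio retained.

## Problem sizes used in validation

The validation suite exercises separations {35, 50, 70, 90, 105} µm at
pixel sizes {2, 5} µm, clean and degraded (noise SD 0.1, 30% dropout), on
96-row strips framing the labeled surface — a realistic field of view that
also keeps the label area fraction in the few-percent regime Otsu needs.
These sizes are this package's own validation choices. Note the 105 µm
separation exceeds the 100 µm matching cap by construction: with parallel
axes 105 µm apart no calcein pixel lies within the cap, every alizarin
pixel is unmatched, and no MAR estimate exists. The suite reports that
sub-case as unmatched rather than raising the cap to manufacture a number.

## Limitations

* The distance estimator is validated on bands; highly branched or
  self-intersecting label geometries will trip the spur pruning and
  end-exclusion heuristics.
* Degenerate growth regions (including single-pair fields) report
  pixel-scale distances and are flagged, not suppressed.
* Otsu thresholding assumes labels occupy a non-trivial area fraction;
  for sparse fields pass a fixed threshold.
* `clean_mask`'s "output within a dilation of the input" property is
  approximate when large ring holes are filled.
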