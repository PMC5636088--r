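# histomar

Automated dynamic bone histomorphometry: mineral apposition rate (MAR) from
alizarin-red / calcein-green double-labeled bone sections, with the
region-of-interest aggregation and study statistics of a multi-group
longitudinal animal study.

## The scientific problem

In dynamic histomorphometry, two fluorochrome dyes are injected a known
number of days apart (here alizarin 8 days and calcein 1 day before
sacrifice, a 7-day interval). Each dye binds the bone surface that was
mineralizing on its injection day, so a section shows two roughly parallel
fluorescent bands wherever bone grew between injections. MAR is the distance
between the band centerlines divided by the interval:

```
MAR (mm/day) = inter-label distance (µm) / interval (days) / 1000
```

Manual measurement draws a handful of calipers per field. `histomar`
measures densely and automatically: channel normalization → thresholding →
mask cleanup → medial-axis skeletonization with spur pruning →
distance-capped (100 µm) nearest-neighbor matching of the two label axes →
a rasterized *growth mask* whose Euclidean distance transform, read along
its own medial axis, gives the local inter-label distance. The package also
ships ROI clipping and per-class pooling (host / callus / junction /
allograft), ICC(2,1), repeated-measures and one-way ANOVA with Tukey HSD,
correlations, fold changes, torque–twist metric extraction, and a synthetic
image/table generator with exact ground truth used to validate all of it.
See the vignette (`vignettes/histomar-methods.Rmd`) for the model and every
numerical design choice.

## Worked example

Generate a degraded synthetic image (true MAR 0.0100 mm/day: 70 µm laid
down over 7 days, with intensity noise and 30% label dropout) and measure
it:

```r
library(histomar)

gen <- generate_double_label_image(
  band_spec(separation_um = 70, band_thickness_um = 10,
            noise_sd = 0.1, gap_fraction = 0.3, seed = 42),
  image_size_px = c(96L, 256L), pixel_size_um = 5
)
res <- run_mar_pipeline(gen$image, pipeline_config(pixel_size_um = 5))
res$mar
#>   region_id mean_mar_mm_per_day sd_mar n_pixels length_um interval_days
#> 1         1          0.01035714      0        3        15             7
#> 2         2          0.01035714      0        7       115             7
#> 3         3          0.01035714      0        7       115             7
#> 4         4          0.01035714      0       37       265             7
#> 5    pooled          0.01035714      0       54       510             7

gen$truth$mar_mm_per_day
#> [1] 0.01
nrow(res$matches$pairs); res$matches$unmatched_fraction
#> [1] 162
#> [1] 0
```

The pooled estimate, 0.01036 mm/day, recovers the 0.0100 mm/day truth
within 3.6% despite noise and dropout.

Study-level statistics on a simulated repeated-measures table (three
groups × three timepoints of callus volume):

```r
tab <- generate_study_table(canine_callus_volume_params(), seed = 1)
fit <- rm_anova_tukey(tab, "callus_volume")
fit$anova
#>       effect df df_error         F            p
#> 1      group  2       14 24.735754 2.540063e-05
#> 2       time  1       14 18.457458 7.389363e-04
#> 3 group:time  2       14  0.582198 5.716372e-01
head(fit$tukey, 3)
#>   timepoint_weeks            contrast      diff         lwr      upr      p_adj
#> 1               4 delayed_pth-control 2455.7274    13.58442 4897.870 0.04866954
#> 2               4         pth-control 2717.0649   274.92183 5159.208 0.02875635
#> 3               4     pth-delayed_pth  261.3374 -2067.15460 2589.829 0.95370318

fold_change(4953, 1854)$fold
#> [1] 2.7
```

A command-line interface wraps the same pipeline
(`inst/cli/histomar.R`, installed under `system.file("cli", "histomar.R",
package = "histomar")`), with subcommands `simulate`, `mar`, and `stats`,
returning exit code 0 on success, 1 on input errors, 2 on internal errors.

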