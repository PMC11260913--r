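# cheeseCT

Quantifying gas-hole ("eye") formation in semi-hard cheese wheels from
volumetric X-ray CT scans.

Eyes — round CO₂-filled cavities formed by propionibacteria and
heterofermentative lactic acid bacteria during ripening — drive the
texture, flavour presentation and market grade of Swiss-type cheeses.
Flat cracks and splits, caused by gas overpressure in an insufficiently
elastic matrix, downgrade a wheel. CT scanning sees both without cutting
the cheese. cheeseCT turns a reconstructed CT volume into defensible
numbers, for dairy technologists and food-imaging researchers who need
eye statistics that are validated rather than eyeballed.

## What it computes

Starting from stored integer CT numbers (offset convention
`ρ = CTN − 1024`, so the 850 kg/m³ segmentation threshold sits at stored
value 1874):

1. **Density conversion** — exact, invertible affine map from stored CT
   numbers to kg/m³ (`ctn_to_density()` / `density_to_ctn()`).
2. **Segmentation** — inclusive density threshold at 850 kg/m³ (cheese
   matrix ≈ 1100–1200 kg/m³); wheel = largest 26-connected cheese
   component; cavities = 6-connected below-threshold components inside
   the wheel's filled interior, with external air removed by boundary
   flood fill and sub-0.01 cm³ speckle discarded.
3. **Morphometry** — per cavity: volume (voxel count × voxel volume,
   identically equal to slice-area × slice-thickness extrapolation),
   surface area (normal-weighted exposed-face estimator), sphericity
   roundness Ψ = π^⅓(6V)^⅔ / A, centroid, and a crack flag
   (Ψ < 0.4 and V > 1 cm³).
4. **Wheel summary** — eye count, mean and 10th/90th-percentile eye
   volume, total eye volume, wheel volume (matrix only),
   Ratio = V_eyes/V_wheel, Eye% = 100·Ratio/(1+Ratio), roundness
   statistics.
5. **Group comparison** — one-way ANOVA + Tukey HSD (α = 0.05) across
   ripening stages or batches, with compact letter display
   (`mean ± sd^letter`).
6. **Phantoms** — synthetic cheese wheels (spherical eyes, planar
   cracks, wax shell, Gaussian density noise) with analytic ground
   truth, used to validate every stage.

## Worked example

Generate a noisy synthetic wheel with 25 eyes of known size, then run
the full analysis:

```r
library(cheeseCT)

spec <- phantom_spec(wheel_radius_mm = 60, wheel_height_mm = 60,
                     n_eyes = 25,
                     eye_radius = list(dist = "uniform", min = 2, max = 8),
                     noise_sd = 20, seed = 7)
ph  <- generate_phantom(spec)          # volume + analytic ground truth
res <- analyze_scan(ph$volume)         # density -> mask -> labels -> summary

res$summary[, c("n_eyes", "mean_eye_volume_cm3", "total_eye_volume_cm3",
                "wheel_volume_cm3", "ratio", "eye_percent",
                "mean_roundness")]
#>   n_eyes mean_eye_volume_cm3 total_eye_volume_cm3 wheel_volume_cm3  ratio
#> 1     25               0.761                   19              672 0.0283
#>   eye_percent mean_roundness
#> 1        2.75           1.01

head(res$catalog[, c("label", "volume_cm3", "surface_area_mm2",
                     "roundness")], 4)
#>   label volume_cm3 surface_area_mm2 roundness
#> 1     1    2.12375         801.5203 0.9968700
#> 2     2    2.09500         794.1493 0.9970218
#> 3     3    2.07875         790.3895 0.9965777
#> 4     4    2.07625         790.1726 0.9960518
```

All 25 generated eyes are recovered despite 20 kg/m³ density noise; the
largest detected cavity (2.124 cm³) matches its generated sphere
(r = 7.98 mm → 2.129 cm³ analytic) to ~0.2 %, and near-spherical eyes score
roundness ≈ 1. Eye% here is 2.75: total eye volume is 2.75 % of the
wheel-plus-eyes volume. Comparing cohorts:

```r
co   <- young_mature_cohorts(n_per_group = 10, seed = 1)
summ <- do.call(rbind, lapply(c(co$young, co$mature),
                              function(p) analyze_scan(p$volume)$summary))
compare_stages(summ, group_by = "age_days")$table
```

prints a `mean ± sd^letter` table per metric: volume metrics separate
the stages (letters a/b), eye counts — drawn from the same Poisson mean —
do not.

A thin CLI wraps the same functions
(`inst/cli/cheesect analyze|compare|phantom ...`), writing per-wheel
`cavities.csv`, `summary.json` (with the full resolved configuration for
provenance) and slice/quarter-section PNG montages.

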