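---
title: "Quantifying eye formation in cheese CT scans: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying eye formation in cheese CT scans: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cheeseCT)
```

## The problem

Eyes — the round gas holes formed by CO~2~ from propionibacteria and
heterofermentative lactic acid bacteria during ripening — are a defining
quality attribute of Swiss-type semi-hard cheeses. A good wheel carries a
balanced mix of small and large eyes distributed through the body; gas
overpressure in a matrix that is too firm instead tears flat cracks and
splits that downgrade the wheel. X-ray computed tomography sees all of
this non-destructively: air-filled voids differ from the protein/fat
matrix by three orders of magnitude in density, so a reconstructed CT
volume separates them almost trivially — *if* the quantification pipeline
downstream of the scanner is trustworthy. cheeseCT is that pipeline, plus
the synthetic phantoms needed to prove it trustworthy without access to
proprietary production scans.

## From CT numbers to density

A reconstructed scan stores an integer CT number per voxel. On the
Hounsfield scale the CT number of a material with linear attenuation
$\mu$ is $1000(\mu - \mu_w)/(\mu_w - \mu_a)$ (water 0, air $-1000$);
scanners store these values with a fixed positive offset. The pipeline
converts stored values to density as

$$\rho \,[\mathrm{kg/m^3}] = \mathrm{CTN}_{stored} - \mathrm{offset},$$

with offset 1024 by default, so the stored value 1874 corresponds to the
segmentation threshold density of 850 kg/m³ and typical cheese matrix
(1100–1200 kg/m³) sits near stored 2124–2224. Two things are worth
stating plainly. First, this affine map is a *calibration convention*,
not a physical density measurement: on it the water-equivalent stored
value 1024 maps to 0, while actual cheese reads in its expected
1100–1200 kg/m³ range — the convention is internally consistent and is
the only reading under which an 850 kg/m³ threshold separates cheese
from air, which is all the segmentation needs. Second, the conversion is
a total, exactly invertible function: `density_to_ctn()` undoes
`ctn_to_density()` bit for bit, and integer stored values survive a
round trip exactly — a property the test suite asserts over the whole
scanner range. Rescale slopes/intercepts found in scan headers are
recorded in the metadata but never silently applied.

## Segmentation

Thresholding is deliberately manual and fixed: a voxel is cheese if
$\rho \ge 850$ kg/m³ (inclusive, so the threshold value itself classes
as cheese). Histogram-automatic methods are attractive when material
properties are unknown, but cheese is a well-characterized, nearly
uniform material and a fixed threshold makes runs comparable across
wheels and time points.

The wheel is the largest 26-connected component of the cheese phase;
everything else above threshold is debris and is dropped (an exact tie
between two largest components is broken toward the smaller linear voxel
index, with a warning). Below-threshold voxels are then partitioned by
connected-component labeling:

* components reachable from the volume boundary are **external air**;
* components inside the wheel's filled interior are **cavities** (eyes,
  cracks, splits);
* cavities smaller than `min_volume_cm3` (default 0.01 cm³, i.e. 8
  voxels at 1 × 1 × 1.25 mm) are discarded as noise speckle and counted
  in the accounting attributes.

Default connectivities are complementary — 26 for the cheese phase, 6
for the air/cavity phase — which avoids the classical topological
paradoxes of using one connectivity for both phases. Labels are assigned
in decreasing volume order. Two eyes that have grown into each other
form one connected component and are counted once (coalescence); a
cavity that opens through the rind is, by construction, connected to
external air and is not counted as an eye. The labeling path is
compiled; an independent plain-R breadth-first flood fill
(`labeling_oracle()`, restricted to ≤ 32³ voxels) reproduces its cavity
partition exactly on randomized volumes in the test suite.

A per-slice labeling mode (`mode = "2d-stacked"`) is provided for
comparison with purely 2D workflows; it reclassifies the same cavity
voxels slice by slice, so total cavity volume is identical and only the
count differs.

## Morphometry

**Volume.** Each cavity's volume is its voxel count times the voxel
volume — algebraically identical to summing per-slice areas and
multiplying by the slice thickness. Both readings are computed with the
same floating-point association so they agree bit for bit, and both are
reported in cm³.

**Surface area.** No analysis-software convention is universal here, so
the estimator is documented precisely: every voxel face separating a
cavity from its complement contributes its physical face area weighted
by $|\hat n_{axis}|$, the corresponding component of the local unit
surface normal, estimated from the gradient of a Gaussian-smoothed copy
of the mask (σ = 1.25 mm, the coarsest voxel dimension). For a planar
interface of any orientation the weighted face sum converges to the true
area, so the estimator is accurate both for spheres (within ~1–3 % at
radii ≥ 4 mm at scan resolution) and for thin planar cracks (within
~15 % for a one-voxel-thick slab, where naive face counting would be off
by 50 %). It is deterministic for fixed input.

**Roundness.** The isoperimetric sphericity
$\Psi = \pi^{1/3}(6V)^{2/3}/A$: exactly 1 for a perfect sphere, well
below 1 for flat or elongated voids. On digitized data the discrete
surface estimate can push $\Psi$ slightly above 1 for small cavities —
a behaviour reported by practitioners of CT cheese morphometry and
reproduced here (a 2 mm digitized sphere scores ≈ 1.03). The package
treats sphericity deviations below ~0.005 at radii ≥ 8 mm as the
estimator's accuracy floor; the convergence test applies that tolerance.

**Crack flagging.** A cavity is flagged as a crack/split candidate when
it is simultaneously irregular (Ψ < 0.4) and large (> 1 cm³). Both
cutoffs are configurable. Flagged cavities remain in the catalog and are
included in eye summaries by default (matching all-cavity reporting);
`include_cracks = FALSE` excludes them.

**Wheel summary.** Per wheel: eye count, mean and 10th/90th-percentile
eye volume (linear interpolation between order statistics), total eye
volume, wheel volume (cheese matrix only, *excluding* cavities),

$$\mathrm{Ratio} = \frac{V_{eyes}}{V_{wheel}}, \qquad
\mathrm{Eye\%} = 100\,\frac{V_{eyes}}{V_{wheel} + V_{eyes}}
             = \frac{100\,\mathrm{Ratio}}{1 + \mathrm{Ratio}},$$

and mean/percentile roundness. A wheel with no cavities reports count,
Ratio and Eye% of zero but *absent* (`NA`) volume and roundness
statistics, so empty wheels do not drag group means toward zero.

## Group statistics

Wheel summaries are compared between groups (ripening stages, batches)
by classical one-way fixed-effects ANOVA with Tukey HSD post-hoc
pairwise comparisons at α = 0.05, delegated to `stats::oneway.test()`
and `stats::TukeyHSD()`. Groups are annotated with a compact letter
display computed by the standard insert-and-absorb algorithm: groups
sharing a letter are not significantly different. Three deliberate
scope choices, mirroring common practice in cheese-quality studies: no
multiple-testing correction across the summary metrics (noted in the
report), no variance-homogeneity testing, and stages treated as
independent groups even when the same wheels are rescanned. With two
groups the Tukey-adjusted p equals the pooled two-sample t-test p (and
the ANOVA p) — asserted to 10⁻⁹ in the tests. A metric with zero
variance everywhere (e.g. identical eye counts) yields an undefined F;
it is reported as non-significant with a single letter rather than
propagating NaNs.

## The phantom generator

Because production scans of commercial wheels are not publicly
deposited, validation rests on synthetic phantoms with analytic ground
truth. A phantom is a cylindrical wheel of uniform density 1150 kg/m³
(mid range for semi-hard cheese) in an air background (1.2 kg/m³),
optionally wrapped in a 930 kg/m³ wax shell, containing:

* **eyes** — spheres with radii from a uniform or lognormal
  distribution, centers uniform in the wheel interior with full
  containment; rejection sampling enforces pairwise non-overlap (with a
  one-voxel guard band so analytically disjoint spheres also stay
  disconnected after rasterization) within 10·n attempts per eye, or
  fails with a placement error;
* **cracks** — thin rectangular slabs with random orientation through
  the wheel interior.

Rasterization uses a voxel-center membership test (no partial-volume
antialiasing): this keeps the analytic oracles exact up to
discretization and matches the sharp-threshold segmentation model. The
density field is forward-converted to stored CT numbers, optionally
degraded with additive white Gaussian density noise, and quantized to
integers. Ground truth records every feature's analytic volume and the
expected number of merged cavity components, computed by sphere/oriented-
box overlap analysis. Everything is deterministic for a fixed seed.

Default geometry (wheel radius 165 mm, height 120 mm, pixel 1 × 1 mm,
slice 1.25 mm) is a realistic full-size wheel at scan resolution; the
validation suite uses a 124.5 mm × 191.25 mm cylinder, which at this
spacing fills a 256 × 256 × 160 grid, and reduced 60 mm wheels for the
20-wheel cohort simulations to keep runtimes in seconds. The cohort
generator draws each wheel's eye count from a Poisson distribution with
a common mean (so counts carry sampling variation but no group effect)
and gives young wheels eye radii ~ U(2, 5) mm versus mature
U(4, 10) mm — eye volume scales with r³, so maturity shows up in every
volume metric but not in the count.

What the phantoms do *not* emulate: partial-volume blur at cavity walls
(available as an optional occupancy mode is deliberately not the
default), beam hardening, scatter, reconstruction artifacts, spatially
correlated noise, and wax/plastic wrap geometry beyond a thin uniform
shell. Passing the phantom suite therefore demonstrates the correctness
of the *analysis* — conversion, segmentation, measurement, statistics —
not the physics of any particular scanner.

## Numerical choices and degenerate inputs

* Threshold comparison inclusive (≥); boundary density classes as cheese.
* Volume identity enforced bit-for-bit by shared multiplication order.
* Percentiles by linear interpolation (`(n-1)q + 1` rule).
* Component-count ties broken by smallest linear voxel index,
  deterministically, with a warning for tied wheels.
* Empty mask → structured no-wheel error; wheel touching all six volume
  faces → field-of-view warning; missing or irregularly spaced slices →
  structured ingest errors naming the offending slices.
* A wax shell (930 kg/m³ ≥ threshold) merges into the wheel component,
  so wheel volume then includes the shell; phantom experiments quantify
  this bias directly. An erosion-based exclusion is a known limitation
  left for future work.
* Stored volumes use one little-endian int32 raw file per slice plus a
  JSON sidecar; integer CT numbers round-trip losslessly.

## Known limitations

Cavity counts from 3D labeling are not comparable to per-slice 2D
counts (the 2d-stacked mode exists precisely to expose that
difference); cracks intersecting eyes merge with them into single
components, as they do physically; and the crack flag is a heuristic on
shape and size, not a classifier trained on real defects. Surface areas
of cavities only a few voxels across are estimator-limited, which is
why roundness there can exceed 1.
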