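---
title: "Quantifying 3D biofilm architecture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D biofilm architecture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmorph)
```

`biofilmorph` quantifies the micron-scale spatial organisation of
surface-attached microbial communities from confocal reflection z-stacks.
This vignette is the package's account of the underlying methods: what each
descriptor measures, which conventions and numerical choices were made where
the field leaves them open, what the synthetic-data generator does and does
not emulate, and where the limits of the approach lie.

## Containers and conventions

A stack is a 3D non-negative intensity array indexed `(z, y, x)` with voxel
calibration `dx`, `dy`, `dz` in µm. The first z slice is the substratum
plane and z increases away from it. Imaging software disagrees on axis
order; fixing `(z, y, x)` once keeps every downstream formula unambiguous.

Thresholding (`binarize()`) converts intensities to a foreground mask.
Foreground is *strictly above* the threshold: this tie-break means an
all-zero stack thresholded at 0 stays exactly empty, which in turn makes the
degenerate anchors of the metric suite exact rather than approximate. The
automatic threshold is Otsu's histogram criterion computed **once over the
whole stack**. A per-slice mode exists (`per_slice = TRUE`), but it is not
the default: slice-wise thresholds adapt to depth-dependent signal loss at
the cost of making voxel counts incomparable across z, and the volumetric
descriptors below all assume one consistent foreground definition.

## The descriptor set

**Biovolume** is the foreground voxel count times the voxel volume.
**Coverage** is reported per cross-section (foreground pixel fraction of a
slice) and as *substratum coverage*: the fraction of `(y, x)` columns
containing any biomass. Growth experiments that report "surface coverage
versus time" are tracking how much of the substratum has been colonised, so
the column-based quantity is what `coverage_fraction()` returns when no
slice is named.

**Area/volume ratio.** The surface area counts foreground voxels with at
least one background (or out-of-bounds) face neighbour — strict
6-connectivity, the tightest reading of "attached to a neighbouring
background pixel" — each weighted by one pixel face area `dx·dy`. That is a
pixel-count surface measure, not a geometric mesh area; an exposed-face
variant (`mode = "faces"`, each exposed face weighted by its own area) is
provided for users who want the stricter geometry. For a solid cube of
`10³` unit voxels the pixel-count convention gives `A/V = 0.488` exactly
(488 boundary voxels of 1000).

**Thickness and roughness fluctuation.** Each column's height is the
topmost foreground voxel, `h = z_top · dz`; internal voids and overhangs
are deliberately ignored, because a reflection-mode height field sees only
the outer surface. A column-sum variant (`mode = "net"`, `dz` per occupied
voxel) is available where occupancy matters more than surface position.
Mean thickness `M` averages `h` over *all* columns by default — empty
columns contribute 0, consistent with averaging "over every point of the
imaging plane" — with `covered_only = TRUE` for the biomass-bearing subset;
the covered-only mean always dominates the default, with equality at full
coverage. The roughness fluctuation coefficient is `η = SD(h)/M`
(population SD over the same column set as `M`). The field also uses
`SD/R_rms` in places; the two coincide only for zero-mean fields, and
`SD/M` is implemented as the primary definition because it is the form
used alongside `M` in morphology reports. `R_rms` itself is available
separately via `rms_roughness()`.

**Boundary fractal dimension.** On a 2D cross-section the boundary set is
every foreground pixel 4-adjacent to an in-image background pixel
(4-connectivity is the 2D analogue of the strict face-adjacency used in
3D). Box counting uses dyadic box sizes `ε = 1, 2, 4, …` up to a quarter of
the shorter side, on a grid anchored at the image origin; `D` is the
least-squares slope of `log N(ε)` against `log(1/ε)`. Grid-offset averaging
would reduce the small-sample bias of box counting but is not implemented —
a documented limitation; anchored counting is deterministic and exactly
reproducible. The report value is clamped to the theoretically meaningful
`[1, 2]` with the raw slope retained as an attribute, since finite-size
effects can push the raw slope slightly past either end. Empty and full
slices have no boundary and error out rather than returning a number.

## Aggregation statistics

Aggregates are 26-connected 3D components: voxels sharing a face, edge or
corner merge, so EPS-bridged colonies in diagonal contact stay one object.
Component volumes conserve total biovolume exactly, and centroids are
z-projected voxel-centre means — the planar positions used for spatial
statistics. Aggregates touching the field border are kept; there is no
edge correction, which biases centroid-based statistics slightly for
patterns dominated by border-clipped objects.

**Hopkins index.** The implemented statistic is `H = Σu²/Σw²` on squared
planar distances: `u_i` from `m` uniformly random sampling locations to
their nearest pattern point, `w_i` from `m` randomly drawn pattern points
to their nearest other point. Under complete spatial randomness both sums
estimate the same quantity and `H ≈ 1`, staying below 2; clustering leaves
large empty regions, inflating `u` and pushing `H` well above 2; regular
(lattice-like) patterns push it below 1. This ratio form matches the
"below 2 random / above 2 patchy" reading used in marine biofilm work. The
classical bounded statistic `Σu²/(Σu²+Σw²) ∈ [0,1]` (0.5 under randomness)
is available as `variant = "classic"`. The index is computed on aggregate
*centroids*, not on raw foreground pixels: pixels of one colony are
trivially clustered, and centroids are what the dispersion question is
about. Sampling noise is controlled by reporting the median of 99
Monte-Carlo repeats (both the repeat count and the seed are explicit
arguments), with `m = min(max(5, ⌈n/10⌉), 50)` by default and `m ≤ n/2`
enforced.

**Aggregation coefficient.** `AC` is the fraction of total biovolume
residing in aggregates individually larger than a volume threshold, 30 µm³
by default. The source literature for this statistic describes its
behaviour — 0 for well-separated uniformly spread cells, 1 when an
excessive EPS matrix fuses everything into large clusters, decreasing under
dispersal agents, with sensitivity tuned by the 30 µm³ threshold — but not
a formula; the above-threshold biovolume fraction is this package's
reconstruction, the simplest statistic reproducing all of that behaviour,
and is flagged as such in the function documentation. It is invariant
under proportional duplication of the above- and sub-threshold populations
(aggregation tendency, not total biomass) and non-decreasing under
aggregate merging.

## Surface descriptors

`rms_roughness()` is the population RMS deviation about the mean plane; no
tilt removal is applied (substrate levelling is out of scope, so tilted
inputs should be corrected upstream). `roughness_factor()` computes the
effective/projected area ratio by splitting each grid cell into two planar
triangles and summing exact triangle areas — exact for piecewise-planar
surfaces, which is why a 45° sawtooth with apexes on grid nodes gives
`√2` to machine precision rather than approximately. Gradient-quadrature
alternatives converge faster on smooth surfaces but are not exact on the
piecewise-planar fixtures used for validation. `extract_profile()` samples
a height map by bilinear interpolation at the pixel pitch along a segment,
mirroring the line-profile workflow of optical profilometry.

## Model fits

`fit_monoexponential()` fits `SR(V) = SReq + A·exp(−V/Vc)`, the saturating
growth of roughness with biovolume: young sparse films are smooth, mature
films approach an equilibrium roughness `SReq` with characteristic volume
`Vc` (kept positive by a box constraint). Fitting is Levenberg–Marquardt
(`minpack.lm`) with data-driven initialisation — `SReq` from the mean SR
over the top V-quartile (the asymptotic region), `A` from the smallest-V
point, `Vc` from a third of the V range — plus two jittered restarts
(multiplicative `U(0.5, 1.5)` under an explicit seed); the converged start
with the lowest residual sum of squares wins. Non-convergence is reported
as such, never silently replaced. A constant-SR series is degenerate in
`Vc`: the fit then returns `A = 0`, `SReq = mean(SR)` and a
"Vc unidentifiable" note, and near-flat series are flagged when the `Vc`
standard error explodes (`> 10·|Vc|`). Parameter recovery at a realistic
operating point (`SReq = 0.36`, `A = −0.34`, `Vc = 2.18·10⁴ µm³`, Gaussian
noise SD 0.01, 200 points with V uniform on `[0, 5Vc]`) is part of the
test suite: across 100 replicates the median absolute error is within
0.01 on `SReq` and 10% on `Vc`.

`fit_sigmoid_coverage()` fits the logistic
`f(t) = f_max/(1+exp(−k(t−t0)))` with `f_max` bounded to `(0, 1]`; a
decreasing series is model-mismatched and is reported either as
non-convergence or with a flagged `k < 0`. The fit-quality `R` reported by
`glance()` is the Pearson correlation between fitted and observed values —
a deliberate, documented choice, since "fit R" is often quoted without
definition. `spearman_rho()` delegates to `stats::cor(method =
"spearman")` (average ranks on ties) and refuses constant input, where
rank correlation is undefined.

## The synthetic-stack generator

`generate_stack()` renders what the estimators assume: substrate-attached
colonies as spherical caps (attached growth is dome-like, not spherical;
cap height is `cap_ratio · r`, default 0.7) with lognormal radii (default
`meanlog = log(3)`, `sdlog = 0.4`, spanning the bacteria-to-algae size
range of a mixed marine community), placed either completely spatially at
random or by a parent–offspring cluster process (uniform parents, isotropic
Gaussian offspring, torus-wrapped to keep intensity uniform). Overlapping
colonies union into one solid — deliberately, since fused colonies are what
multi-scale aggregate statistics must cope with. Optional halos at reduced
relative intensity emulate low-density amorphous EPS around colonies;
optional sinusoidal corrugation (default period 20 µm, depth 6 µm, the
scale of sandpaper-grooved metal substrates) raises colonies onto a
substrate height field. Rendering is voxel-centre inclusion on the integer
grid, noise is additive Gaussian clamped at zero, and every stack is a
deterministic function of its seed (bit-identical across runs).

The ground truth record carries exact per-colony geometry, the analytic
cap volume `πh²(3r−h)/3`, and the voxel-exact solid volume, so estimator
error can be separated into discretisation error (truth mask vs analytic
volume, within 3% at 0.25 µm voxels for a 10 µm cap and shrinking with
voxel size) and thresholding error (recovered mask vs truth mask, Jaccard
> 0.9 at SNR 5 with global Otsu). A density guard rejects specs whose
ground truth would cover more than 95% of the substratum, where
coverage-based statistics saturate.

What the generator does **not** emulate: depth-dependent attenuation and
the confocal point-spread function, multi-channel stains, the silica/
inorganic reflective fraction that dominates some field samples, and
non-spherical organism geometry (diatom frustules). Passing tests therefore
demonstrate correctness of the measurement pipeline on known geometry, not
robustness to every optical artefact of field microscopy.

`generate_growth_series()` produces seasonal coverage and AC time courses
on the standard 2–20 day collection schedule (sampled every 2 days):
logistic curves with plateaus drawn once per scenario — April
`U(0.38, 0.41)`, August `U(0.42, 0.45)`, November `U(0.05, 0.06)` — a lag
consistent with growth accelerating after 5–6 days (midpoint
`t0 ~ U(7.5, 8.5)` days, rate `k ~ U(0.6, 0.8) d⁻¹`; November slower,
`k ~ U(0.3, 0.5)`, `t0 ~ U(8, 10)`), and observation noise of SD 0.02
(0.005 in November, where coverage itself is only a few percent). The
companion AC series is the noise-free logistic shifted 2 days after the
coverage midpoint — structural compaction follows colonisation — and is
therefore non-decreasing by construction.

## Validation strategy and problem sizes

Every closed-form metric is tested against an independent brute-force
implementation (naive loops, kept in the test helpers, never shared with
package code) on randomized masks of 16³–32³ voxels across 100 seeds, and
against analytic fixtures: the 488-voxel cube boundary, the spherical-cap
volume, `√2` for the sawtooth roughness factor, `a/√2` for a sine profile
RMS. Dispersion statistics are anchored behaviourally: AC exactly 0 on a
60-colony dispersed sub-threshold field (300×300 µm, 0.5 µm voxels) and
exactly 1 on a single 20×20×10 µm block; the Hopkins median below 2 for
500 CSR points and far above 2 for a 20-parent, σ = 2 µm cluster process
in a 500×500 µm window. These sizes keep the full suite under a minute of
computation per module while leaving each estimator no room to be right by
accident.

## Known limitations

- Box counting without grid-offset averaging biases `D` slightly upward on
  coarse boundaries.
- No edge correction in aggregate and point-pattern statistics.
- Thickness ignores overhangs by design; films with true internal voids
  need the `"net"` height mode and care in interpreting `η`.
- `R_rms` assumes a levelled substrate (no tilt removal).
- The Otsu threshold assumes a bimodal intensity histogram; heavily skewed
  stacks (sparse bright biomass over dominant background) can push the
  global threshold low, and a fixed threshold may serve better.
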