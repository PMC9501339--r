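# biofilmorph

Quantification of the three-dimensional architecture of surface-attached
microbial biofilms from calibrated confocal image stacks.

Marine biofilms — mixed communities of bacteria, diatoms and other
micro-algae glued to submerged surfaces by extracellular polymeric
substances (EPS) — organise at the micron scale, and their structure
responds measurably to season, substratum roughness, wettability and
nutrient status. `biofilmorph` computes the standard geometric and
structural descriptors used to track that organisation in reflection-mode
confocal z-stacks, and ships a synthetic stack generator with exact ground
truth so the whole pipeline can be validated without microscope data.

## Descriptors

For a calibrated binary stack (voxel `dx × dy × dz` µm, substratum at the
first z slice):

- **Biovolume** `V = N_fg · dx·dy·dz` (µm³), with `N_fg` the foreground
  voxel count.
- **Coverage fraction** `f`: foreground pixel fraction of a cross-section,
  or the substratum coverage (fraction of columns holding any biomass).
- **Area/volume ratio** `A/V` (µm⁻¹): `A` counts foreground voxels
  face-adjacent to background, weighted by the pixel face area.
- **Mean thickness** `M` (µm): mean of the per-column top heights `h`.
- **Roughness fluctuation coefficient** `η = SD(h)/M` (dimensionless).
- **Boundary fractal dimension** `D ∈ [1, 2]`: box-counting slope of
  `log N(ε)` vs `log(1/ε)` on the 2D biomass/background boundary of a
  cross-section.
- **Hopkins aggregation index** `H = Σu²/Σw²`: empty-space versus
  nearest-neighbour distances of aggregate centroids, median over 99
  Monte-Carlo repeats; `H < 2` for randomly dispersed colonies, `H > 2`
  for patchy ones.
- **Aggregation coefficient** `AC ∈ [0, 1]`: fraction of biovolume in
  26-connected aggregates larger than 30 µm³ — 0 for fully dispersed
  communities, 1 for a single large cluster.

Substrate descriptors (`rms_roughness`, `roughness_factor`,
`extract_profile`) cover profilometry-style analyses: RMS height
deviation, effective/projected area ratio `R_f ≥ 1`, and line profiles.
Model fits (`fit_monoexponential` for `SR(V) = SReq + A·exp(−V/Vc)`,
`fit_sigmoid_coverage` for logistic coverage-vs-time, `spearman_rho` for
rank correlations) relate the descriptors to growth.

## Worked example

```r
library(biofilmorph)

# a clustered colony field, 150 x 150 um at 0.5 um voxels, with noise
sim <- generate_stack(synthetic_spec(
  width = 150, length = 150, dx = 0.5, dy = 0.5, dz = 0.5,
  n_colonies = 60, placement = "clustered", n_parents = 12,
  offspring_sigma = 8, radius_meanlog = log(4), radius_sdlog = 0.4,
  noise_sd = 10, seed = 42))

mask <- binarize(sim$stack, "otsu")
mask
#> <binary_grid> 14 slices x 300 x 300 px | voxel 0.5 x 0.5 x 0.5 um | 56302 foreground voxels (4.47%)

morphology_report(mask, seed = 1)
#>   biovolume_um3 coverage_pct area_to_volume_per_um mean_thickness_um
#> 1          7038         12.2                 0.794             0.313
#>   roughness_coefficient fractal_dimension hopkins_index aggregation_coefficient
#> 1                  3.09               1.1          1.49                   0.991
```

7038 µm³ of biomass covers 12.2% of the substratum; the near-1 fractal
dimension says colony outlines are smooth at this density, and AC ≈ 0.99
says almost all biomass sits in aggregates above the 30 µm³ threshold —
the clustered placement fused colonies into large connected structures.

Growth curves fit the same way:

```r
g <- generate_growth_series("august", seed = 7)
fit <- fit_sigmoid_coverage(g$coverage)
tidy(fit)
#> # A tibble: 3 x 3
#>   term  estimate std.error
#> 1 f_max    0.475   0.00983
#> 2 k        0.682   0.0770
#> 3 t0       8.02    0.192
```

— a coverage plateau near 47%, reached with rate 0.68 d⁻¹ around day 8.
Every fitted object supports `tidy()`, `glance()` and `autoplot()`;
height maps, point patterns and growth series have `autoplot()` methods
too. A thin command-line front end is installed as `exec/biofilmtools`
(subcommands `analyze`, `fit`, `simulate`).

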