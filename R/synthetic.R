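# Synthetic confocal stacks, point patterns and growth series with exact
# ground truth, emulating reflection-mode images of surface-attached
# colonies.

#' Specification for a synthetic confocal stack
#'
#' Describes a field of substrate-attached colonies rendered as spherical
#' caps (colonies grow dome-like from the substratum, not as free spheres)
#' with lognormally distributed radii spanning the size range of a mixed
#' marine community (bacteria ~1 um up to algae ~25 um), placed either
#' completely spatially at random or as a clustered parent-offspring
#' process. Optional low-intensity halos emulate amorphous EPS around
#' colonies; optional sinusoidal grooves emulate sandpaper-abraded substrate
#' corrugation (valleys a few um deep, ridges 5-25 um apart). Rendering adds
#' Gaussian noise and clamps intensities at 0.
#'
#' @param width,length Field extent in um (x, y).
#' @param dx,dy,dz Voxel calibration in um.
#' @param n_slices Number of z slices; `NULL` (default) auto-sizes to the
#'   tallest rendered structure.
#' @param n_colonies Number of colonies.
#' @param placement `"csr"` or `"clustered"`.
#' @param n_parents,offspring_sigma Parent count and isotropic Gaussian
#'   scatter (um) for clustered placement.
#' @param radius_meanlog,radius_sdlog Lognormal colony-radius parameters
#'   (log-um scale); `radius_sdlog = 0` gives identical radii.
#' @param cap_ratio Cap height as a fraction of colony radius, in (0, 1].
#' @param intensity Solid colony intensity (arbitrary units).
#' @param halo_intensity Halo intensity relative to `intensity` (0 disables).
#' @param halo_thickness Halo shell thickness in um.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param substrate `"flat"` or `"grooves"`.
#' @param groove_period,groove_depth Groove wavelength and peak-to-valley
#'   depth in um.
#' @param seed Integer RNG seed (mandatory: every stack is reproducible).
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_stack()]
#' @export
synthetic_spec <- function(width = 300, length = 300,
                           dx = 0.5, dy = 0.5, dz = 1, n_slices = NULL,
                           n_colonies = 60,
                           placement = c("csr", "clustered"),
                           n_parents = 20, offspring_sigma = 10,
                           radius_meanlog = log(3), radius_sdlog = 0.4,
                           cap_ratio = 0.7,
                           intensity = 100, halo_intensity = 0,
                           halo_thickness = 0, noise_sd = 10,
                           substrate = c("flat", "grooves"),
                           groove_period = 20, groove_depth = 6,
                           seed = 1L) {
  placement <- match.arg(placement)
  substrate <- match.arg(substrate)
  stopifnot(width > 0, length > 0, dx > 0, dy > 0, dz > 0,
            n_colonies >= 0, cap_ratio > 0, cap_ratio <= 1,
            intensity > 0, halo_intensity >= 0, halo_intensity < 1,
            halo_thickness >= 0, noise_sd >= 0,
            groove_period > 0, groove_depth >= 0)
  if (is.null(seed)) abort("a `seed` is mandatory for reproducible stacks.")
  structure(list(width = width, length = length, dx = dx, dy = dy, dz = dz,
                 n_slices = n_slices, n_colonies = n_colonies,
                 placement = placement, n_parents = n_parents,
                 offspring_sigma = offspring_sigma,
                 radius_meanlog = radius_meanlog, radius_sdlog = radius_sdlog,
                 cap_ratio = cap_ratio, intensity = intensity,
                 halo_intensity = halo_intensity,
                 halo_thickness = halo_thickness, noise_sd = noise_sd,
                 substrate = substrate, groove_period = groove_period,
                 groove_depth = groove_depth, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Analytic spherical-cap volume: pi h^2 (3 r - h) / 3.
cap_volume <- function(r, h) pi * h^2 * (3 * r - h) / 3

substrate_height <- function(spec, x) {
  if (spec$substrate == "flat") rep(0, length(x))
  else spec$groove_depth / 2 * (1 + sin(2 * pi * x / spec$groove_period))
}

#' Render a synthetic confocal stack with ground truth
#'
#' Places colonies per the spec, renders each as a spherical cap sitting on
#' the local substrate height (overlapping colonies union into one solid),
#' adds an optional EPS halo shell at reduced intensity, then Gaussian noise.
#' The same seed always yields a bit-identical stack.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `stack` (noisy [voxel_grid()]),
#'   `truth_mask` (noise-free solid [binary_grid()]), and `truth`: a list
#'   with the per-colony tibble (`x`, `y`, `r`, `cap_height`,
#'   `volume_analytic_um3`), `solid_volume_um3` (voxel-exact), the summed
#'   `analytic_volume_um3` (exact when colonies do not overlap),
#'   `substratum_coverage` and the spec.
#' @examples
#' out <- generate_stack(synthetic_spec(width = 60, length = 60,
#'                                      n_colonies = 5, seed = 3))
#' out$truth$solid_volume_um3
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nx <- round(spec$width / spec$dx)
  ny <- round(spec$length / spec$dy)
  withr::with_seed(spec$seed, {
    # colony centres
    n <- spec$n_colonies
    if (n > 0) {
      if (spec$placement == "csr") {
        x0 <- runif(n, 0, spec$width)
        y0 <- runif(n, 0, spec$length)
      } else {
        px <- runif(spec$n_parents, 0, spec$width)
        py <- runif(spec$n_parents, 0, spec$length)
        pa <- sample.int(spec$n_parents, n, replace = TRUE)
        x0 <- (px[pa] + rnorm(n, 0, spec$offspring_sigma)) %% spec$width
        y0 <- (py[pa] + rnorm(n, 0, spec$offspring_sigma)) %% spec$length
      }
      r <- rlnorm(n, spec$radius_meanlog, spec$radius_sdlog)
      hc <- spec$cap_ratio * r
      zb <- substrate_height(spec, x0)
    } else {
      x0 <- y0 <- r <- hc <- zb <- numeric(0)
    }
    nz <- spec$n_slices %||%
      max(4L, ceiling((max(c(zb + hc, spec$groove_depth, 1)) +
                       spec$halo_thickness) / spec$dz) + 1L)
    mask <- array(FALSE, c(nz, ny, nx))
    halo <- array(FALSE, c(nz, ny, nx))
    zc <- (seq_len(nz) - 0.5) * spec$dz  # voxel-centre heights
    for (i in seq_along(x0)) {
      rr <- r[i] + spec$halo_thickness
      ix <- seq(max(1L, floor((x0[i] - rr) / spec$dx)),
                min(nx, ceiling((x0[i] + rr) / spec$dx) + 1L))
      iy <- seq(max(1L, floor((y0[i] - rr) / spec$dy)),
                min(ny, ceiling((y0[i] + rr) / spec$dy) + 1L))
      iz <- which(zc >= zb[i] & zc <= zb[i] + hc[i] + spec$halo_thickness)
      if (!length(ix) || !length(iy) || !length(iz)) next
      xs <- (ix - 0.5) * spec$dx - x0[i]
      ys <- (iy - 0.5) * spec$dy - y0[i]
      zs <- zc[iz] - (zb[i] + hc[i] - r[i])  # z relative to sphere centre
      d2 <- outer(outer(zs^2, ys^2, "+"), xs^2, "+")  # (z, y, x) block
      mask[iz, iy, ix] <- mask[iz, iy, ix, drop = FALSE] | (d2 <= r[i]^2)
      if (spec$halo_intensity > 0 && spec$halo_thickness > 0)
        halo[iz, iy, ix] <- halo[iz, iy, ix, drop = FALSE] | (d2 <= rr^2)
    }
    halo <- halo & !mask
    cov <- mean(apply(mask, c(2, 3), any))
    if (cov > 0.95)
      abort(sprintf(
        "colony density too high: substratum coverage %.1f%% exceeds 95%%.",
        100 * cov))
    intens <- array(0, c(nz, ny, nx))
    intens[mask] <- spec$intensity
    intens[halo] <- spec$halo_intensity * spec$intensity
    if (spec$noise_sd > 0)
      intens <- pmax(intens + rnorm(base::length(intens), 0, spec$noise_sd), 0)
    colonies <- tibble(x = x0, y = y0, r = r, cap_height = hc,
                       volume_analytic_um3 = cap_volume(r, hc))
    list(
      stack = voxel_grid(intens, spec$dx, spec$dy, spec$dz),
      truth_mask = binary_grid(mask, spec$dx, spec$dy, spec$dz),
      truth = list(colonies = colonies,
                   solid_volume_um3 = sum(mask) * spec$dx * spec$dy * spec$dz,
                   analytic_volume_um3 = sum(colonies$volume_analytic_um3),
                   substratum_coverage = cov,
                   spec = spec)
    )
  })
}

#' Generate a planar point pattern
#'
#' Simulates point patterns for dispersion statistics: `"csr"` draws
#' uniform iid points (complete spatial randomness), `"clustered"` a
#' parent-offspring process (uniform parents, isotropic Gaussian offspring
#' scatter, torus-wrapped), `"grid"` a regular lattice of cell centres.
#'
#' @param mode `"csr"`, `"clustered"` or `"grid"`.
#' @param n Number of points.
#' @param window Window extent `c(W, L)` in um.
#' @param seed Integer RNG seed.
#' @param n_parents,sigma Clustered-mode parent count and offspring scatter
#'   SD (um).
#' @return A [point_pattern_2d()].
#' @export
generate_point_pattern <- function(mode = c("csr", "clustered", "grid"),
                                   n, window = c(500, 500), seed = 1L,
                                   n_parents = 20, sigma = 2) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, length(window) == 2L, all(window > 0))
  if (mode == "grid") {
    kx <- round(sqrt(n))
    ky <- ceiling(n / kx)
    gx <- (seq_len(kx) - 0.5) * window[1] / kx
    gy <- (seq_len(ky) - 0.5) * window[2] / ky
    g <- expand.grid(x = gx, y = gy)[seq_len(n), ]
    return(point_pattern_2d(g$x, g$y, window))
  }
  withr::with_seed(seed, {
    if (mode == "csr") {
      x <- runif(n, 0, window[1]); y <- runif(n, 0, window[2])
    } else {
      px <- runif(n_parents, 0, window[1])
      py <- runif(n_parents, 0, window[2])
      pa <- sample.int(n_parents, n, replace = TRUE)
      x <- (px[pa] + rnorm(n, 0, sigma)) %% window[1]
      y <- (py[pa] + rnorm(n, 0, sigma)) %% window[2]
    }
    point_pattern_2d(x, y, window)
  })
}

#' Generate seasonal growth series
#'
#' Simulates substratum-coverage and aggregation-coefficient time courses
#' over the standard collection schedule (days 2, 4, ..., 20), reproducing
#' the seasonal regimes observed in Baltic coastal deployments: productive
#' seasons plateau near 38-45% coverage after a 5-6 day lag, while the
#' late-autumn regime stays below 5-6%; the companion AC series rises as the
#' community compacts into aggregates after the coverage plateau sets in.
#' Coverage carries additive observation noise (clamped to `[0, 1]`); the AC
#' series is the noise-free logistic, hence non-decreasing by construction.
#'
#' @param scenario `"april"`, `"august"` or `"november"`.
#' @param seed Integer RNG seed.
#' @param noise_sd Coverage observation noise SD; `NULL` uses the scenario
#'   default (0.02, or 0.005 in November where coverage is tiny); 0 gives
#'   exact logistic values.
#' @return A list with `coverage` and `ac` ([growth_series()] objects) and
#'   `params`, the true curve parameters.
#' @export
generate_growth_series <- function(scenario = c("april", "august", "november"),
                                   seed = 1L, noise_sd = NULL) {
  scenario <- match.arg(scenario)
  t <- seq(2, 20, by = 2)
  withr::with_seed(seed, {
    par <- switch(scenario,
      april    = list(f_max = runif(1, 0.38, 0.41), k = runif(1, 0.6, 0.8),
                      t0 = runif(1, 7.5, 8.5), ac_max = runif(1, 0.4, 0.6),
                      default_noise = 0.02),
      august   = list(f_max = runif(1, 0.42, 0.45), k = runif(1, 0.6, 0.8),
                      t0 = runif(1, 7.5, 8.5), ac_max = runif(1, 0.4, 0.6),
                      default_noise = 0.02),
      november = list(f_max = runif(1, 0.05, 0.06), k = runif(1, 0.3, 0.5),
                      t0 = runif(1, 8, 10), ac_max = runif(1, 0.08, 0.15),
                      default_noise = 0.005))
    sdn <- noise_sd %||% par$default_noise
    f <- par$f_max / (1 + exp(-par$k * (t - par$t0)))
    if (sdn > 0) f <- pmin(pmax(f + rnorm(length(t), 0, sdn), 0), 1)
    ac <- par$ac_max / (1 + exp(-par$k * (t - (par$t0 + 2))))
    list(coverage = growth_series(t, f, metric = "coverage", units = ""),
         ac = growth_series(t, ac, metric = "ac", units = ""),
         params = par)
  })
}
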