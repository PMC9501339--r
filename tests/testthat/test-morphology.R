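test_that("biovolume counts voxels times voxel volume", {
  m <- array(FALSE, c(2, 4, 4))
  m[1, 1:2, 1:2] <- TRUE; m[2, 1:2, 1:2] <- TRUE
  expect_equal(biovolume(binary_grid(m, 0.5, 0.5, 1)), 2.0)
  expect_equal(biovolume(binary_grid(array(FALSE, c(2, 4, 4)), 1, 1, 1)), 0)
})

test_that("voxelized spherical cap recovers the analytic volume within 3%", {
  sp <- synthetic_spec(width = 40, length = 40, dx = 0.25, dy = 0.25,
                       dz = 0.25, n_colonies = 1, radius_meanlog = log(10),
                       radius_sdlog = 0, cap_ratio = 0.6, noise_sd = 0,
                       seed = 5)
  out <- generate_stack(sp)
  v_analytic <- cap_vol(10, 6)
  expect_equal(out$truth$colonies$volume_analytic_um3, v_analytic)
  expect_lt(abs(biovolume(out$truth_mask) - v_analytic) / v_analytic, 0.03)
})

test_that("coverage_fraction handles full, half and per-slice cases", {
  m <- array(FALSE, c(2, 8, 8))
  m[1, , ] <- TRUE
  bg <- binary_grid(m, 1, 1, 1)
  expect_equal(coverage_fraction(bg, z = 1), 1.0)
  expect_equal(coverage_fraction(bg, z = 2), 0.0)
  expect_equal(coverage_fraction(bg), 1.0)  # substratum coverage
  m2 <- array(FALSE, c(1, 8, 8)); m2[1, , 1:4] <- TRUE
  expect_equal(coverage_fraction(binary_grid(m2, 1, 1, 1), z = 1), 0.5)
  expect_error(coverage_fraction(bg, z = 3), "1..2")
})

test_that("area_to_volume matches hand geometry for voxel and cube", {
  m <- array(FALSE, c(3, 4, 4)); m[2, 2, 2] <- TRUE
  expect_equal(area_to_volume(binary_grid(m, 1, 1, 1)), 1.0)
  cube <- array(FALSE, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- TRUE
  expect_equal(area_to_volume(binary_grid(cube, 1, 1, 1)), 0.488)
  expect_error(area_to_volume(binary_grid(array(FALSE, c(2, 4, 4)), 1, 1, 1)),
               "empty")
})

test_that("thickening a slab strictly decreases its area/volume ratio", {
  slab1 <- array(FALSE, c(8, 10, 10)); slab1[1:2, , ] <- TRUE
  slab2 <- array(FALSE, c(8, 10, 10)); slab2[1:4, , ] <- TRUE
  av1 <- area_to_volume(binary_grid(slab1, 1, 1, 1))
  av2 <- area_to_volume(binary_grid(slab2, 1, 1, 1))
  expect_lt(av2, av1)
})

test_that("height map takes the topmost foreground and ignores voids", {
  slab <- array(FALSE, c(10, 6, 6)); slab[1:10, , ] <- TRUE
  hm <- height_map(binary_grid(slab, 1, 1, 1))
  expect_true(all(hm$h == 10))
  empty <- height_map(binary_grid(array(FALSE, c(2, 4, 4)), 1, 1, 1))
  expect_true(all(empty$h == 0))
  # internal voids: top surface is what counts
  for (s in 1:5) {
    bg <- rand_mask(s, d = c(8, 10, 10), p = 0.3, dx = 1, dy = 1, dz = 0.7)
    expect_equal(height_map(bg)$h, bf_top_height(bg))
  }
})

test_that("net-height mode counts occupied voxels per column", {
  m <- array(FALSE, c(5, 4, 4))
  m[c(1, 3, 5), 1, 1] <- TRUE  # column with voids
  hm <- height_map(binary_grid(m, 1, 1, 2), mode = "net")
  expect_equal(hm$h[1, 1], 6)  # 3 voxels x dz = 2
  expect_equal(height_map(binary_grid(m, 1, 1, 2))$h[1, 1], 10)  # top at z=5
})

test_that("mean thickness averages all columns by default, covered on request", {
  h <- matrix(0, 8, 8); h[, 1:4] <- 10
  hm <- make_height_map(h)
  expect_equal(mean_thickness(hm), 5)
  expect_equal(mean_thickness(hm, covered_only = TRUE), 10)
  for (s in 1:5) {
    bg <- rand_mask(s + 20, d = c(6, 12, 12), p = 0.4)
    ms <- bf_mean_sd(bf_top_height(bg))
    expect_equal(mean_thickness(height_map(bg)), unname(ms["mean"]))
  }
})

test_that("covered-only thickness dominates the default, equal at full coverage", {
  for (s in 1:5) {
    bg <- rand_mask(s + 40, d = c(6, 10, 10), p = 0.4)
    hm <- height_map(bg)
    if (!any(hm$covered)) next
    expect_gte(mean_thickness(hm, covered_only = TRUE), mean_thickness(hm))
  }
  full <- array(TRUE, c(3, 6, 6))
  hm <- height_map(binary_grid(full, 1, 1, 1))
  expect_equal(mean_thickness(hm, covered_only = TRUE), mean_thickness(hm))
})

test_that("roughness coefficient is population SD over mean of the heights", {
  flat <- make_height_map(matrix(7, 8, 8))
  expect_equal(roughness_coefficient(flat), 0)
  h <- matrix(2, 8, 8); h[, 1:4] <- 6  # two-point distribution h and 3h
  expect_equal(roughness_coefficient(make_height_map(h)), 0.5)
  for (s in 1:5) {
    bg <- rand_mask(s + 60, d = c(6, 12, 12), p = 0.6)
    ms <- bf_mean_sd(bf_top_height(bg))
    expect_equal(roughness_coefficient(height_map(bg)),
                 unname(ms["sd"] / ms["mean"]))
  }
  expect_error(roughness_coefficient(make_height_map(matrix(0, 8, 8))),
               "undefined")
})

test_that("fractal dimension of a straight-boundary square is close to 1", {
  sl <- matrix(FALSE, 256, 256); sl[79:178, 79:178] <- TRUE
  d <- fractal_dimension_2d(sl)
  expect_lt(abs(as.numeric(d) - 1), 0.1)
  expect_equal(attr(d, "raw"), bf_box_dimension(sl), tolerance = 1e-10)
})

test_that("reported fractal dimension stays within [1, 2] on synthetic slices", {
  out <- generate_stack(synthetic_spec(width = 60, length = 60, dx = 0.5,
                                       dy = 0.5, dz = 0.5, n_colonies = 15,
                                       noise_sd = 0, seed = 31))
  m <- out$truth_mask$mask
  tested <- 0L
  for (z in seq_len(dim(m)[1])) {
    sl <- m[z, , ]
    if (!any(sl) || all(sl)) next
    d <- fractal_dimension_2d(sl)
    expect_gte(as.numeric(d), 1); expect_lte(as.numeric(d), 2)
    tested <- tested + 1L
  }
  expect_gt(tested, 0L)
  expect_error(fractal_dimension_2d(matrix(TRUE, 16, 16)), "undefined")
  expect_error(fractal_dimension_2d(matrix(FALSE, 16, 16)), "undefined")
})

test_that("fractal dimension is stable under 2x nearest-neighbour upscaling", {
  out <- generate_stack(synthetic_spec(width = 50, length = 50, dx = 0.5,
                                       dy = 0.5, dz = 0.5, n_colonies = 10,
                                       noise_sd = 0, seed = 33))
  sl <- out$truth_mask$mask[1, , ]
  skip_if(!any(sl) || all(sl))
  up <- sl[rep(seq_len(nrow(sl)), each = 2), rep(seq_len(ncol(sl)), each = 2)]
  d1 <- as.numeric(fractal_dimension_2d(sl))
  d2 <- as.numeric(fractal_dimension_2d(up))
  expect_lt(abs(d1 - d2), 0.1)
})

test_that("biovolume equals the coverage-slice sum identity", {
  for (s in 1:5) {
    bg <- rand_mask(s + 80, d = c(5, 10, 14))
    d <- dim(bg$mask)
    slice_area <- d[2] * d[3] * bg$dx * bg$dy
    v <- sum(vapply(seq_len(d[1]),
                    function(z) coverage_fraction(bg, z), numeric(1))) *
      slice_area * bg$dz
    expect_equal(biovolume(bg), v)
  }
})

test_that("metrics are invariant under x-y transposition", {
  bg <- rand_mask(99, d = c(5, 10, 14), p = 0.4, dx = 0.7, dy = 0.7, dz = 1)
  tm <- aperm(bg$mask, c(1, 3, 2))
  bgt <- binary_grid(tm, bg$dy, bg$dx, bg$dz)
  expect_equal(biovolume(bgt), biovolume(bg))
  expect_equal(coverage_fraction(bgt), coverage_fraction(bg))
  expect_equal(area_to_volume(bgt), area_to_volume(bg))
  expect_equal(mean_thickness(height_map(bgt)), mean_thickness(height_map(bg)))
  expect_equal(roughness_coefficient(height_map(bgt)),
               roughness_coefficient(height_map(bg)))
})

test_that("morphology_report returns the fixed schema and writes JSON/CSV", {
  out <- generate_stack(synthetic_spec(width = 80, length = 80, dx = 0.5,
                                       dy = 0.5, dz = 0.5, n_colonies = 25,
                                       radius_meanlog = log(3),
                                       noise_sd = 0, seed = 41))
  rep <- morphology_report(out$truth_mask, seed = 1)
  expect_named(rep, c("biovolume_um3", "coverage_pct", "area_to_volume_per_um",
                      "mean_thickness_um", "roughness_coefficient",
                      "fractal_dimension", "hopkins_index",
                      "aggregation_coefficient"))
  expect_equal(rep$biovolume_um3, biovolume(out$truth_mask))
  expect_true(rep$coverage_pct >= 0 && rep$coverage_pct <= 100)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, jp); write_report(rep, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$biovolume_um3, rep$biovolume_um3)
  expect_equal(nrow(utils::read.csv(cp)), 1L)
})
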