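test_that("an empty spec yields an empty ground-truth mask", {
  out <- generate_stack(synthetic_spec(width = 20, length = 20, n_colonies = 0,
                                       noise_sd = 0, seed = 1))
  expect_false(any(out$truth_mask$mask))
  expect_equal(out$truth$solid_volume_um3, 0)
  expect_equal(nrow(out$truth$colonies), 0L)
})

test_that("a finely voxelized cap matches its analytic volume within 3%", {
  out <- generate_stack(synthetic_spec(width = 40, length = 40, dx = 0.25,
                                       dy = 0.25, dz = 0.25, n_colonies = 1,
                                       radius_meanlog = log(10),
                                       radius_sdlog = 0, cap_ratio = 0.6,
                                       noise_sd = 0, seed = 5))
  expect_lt(abs(out$truth$solid_volume_um3 - cap_vol(10, 6)) / cap_vol(10, 6),
            0.03)
})

test_that("volume error shrinks as voxels shrink", {
  err <- vapply(c(1, 0.5, 0.25), function(vx) {
    out <- generate_stack(synthetic_spec(width = 40, length = 40, dx = vx,
                                         dy = vx, dz = vx, n_colonies = 1,
                                         radius_meanlog = log(8),
                                         radius_sdlog = 0, cap_ratio = 0.7,
                                         noise_sd = 0, seed = 2))
    abs(out$truth$solid_volume_um3 - cap_vol(8, 5.6)) / cap_vol(8, 5.6)
  }, numeric(1))
  expect_true(err[3] < err[1])
})

test_that("identical seeds give bit-identical stacks, different seeds differ", {
  sp <- synthetic_spec(width = 40, length = 40, n_colonies = 8, noise_sd = 5,
                       seed = 77)
  a <- generate_stack(sp)
  b <- generate_stack(sp)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth_mask$mask, b$truth_mask$mask)
  sp2 <- synthetic_spec(width = 40, length = 40, n_colonies = 8, noise_sd = 5,
                        seed = 78)
  expect_false(identical(generate_stack(sp2)$stack$data, a$stack$data))
})

test_that("binarizing a noiseless rendering at half intensity reproduces truth", {
  out <- generate_stack(synthetic_spec(width = 50, length = 50, n_colonies = 10,
                                       noise_sd = 0, halo_intensity = 0.3,
                                       halo_thickness = 1, intensity = 100,
                                       seed = 12))
  bg <- binarize(out$stack, "fixed", threshold = 50)
  expect_identical(bg$mask, out$truth_mask$mask)
})

test_that("excessive colony density is rejected", {
  sp <- synthetic_spec(width = 20, length = 20, n_colonies = 400,
                       radius_meanlog = log(6), radius_sdlog = 0,
                       noise_sd = 0, seed = 3)
  expect_error(generate_stack(sp), "coverage")
})

test_that("grooved substrates lift colonies onto the corrugation", {
  flat <- generate_stack(synthetic_spec(width = 60, length = 60,
                                        n_colonies = 20, noise_sd = 0,
                                        substrate = "flat", seed = 9))
  gro <- generate_stack(synthetic_spec(width = 60, length = 60,
                                       n_colonies = 20, noise_sd = 0,
                                       substrate = "grooves",
                                       groove_period = 20, groove_depth = 6,
                                       seed = 9))
  h_flat <- max(height_map(flat$truth_mask)$h)
  h_gro <- max(height_map(gro$truth_mask)$h)
  expect_gt(h_gro, h_flat)  # same colonies, raised by the height field
})

test_that("grid point patterns form the exact lattice", {
  pp <- generate_point_pattern("grid", 100, c(100, 100))
  pts <- tidy(pp)
  expect_equal(nrow(pts), 100L)
  expect_equal(sort(unique(pts$x)), (1:10 - 0.5) * 10)
  expect_equal(sort(unique(pts$y)), (1:10 - 0.5) * 10)
})

test_that("CSR intensity matches nominal within 3 SD over many seeds", {
  n <- 200; W <- 400
  # count points in the left half-window: Binomial(n, 1/2)
  counts <- vapply(1:100, function(s) {
    pp <- generate_point_pattern("csr", n, c(W, W), seed = s)
    sum(tidy(pp)$x < W / 2)
  }, numeric(1))
  expect_lt(abs(mean(counts) - n / 2), 3 * sqrt(n * 0.25) / sqrt(100))
})

test_that("clustered placement with huge scatter degenerates to CSR by Hopkins", {
  meds_cl <- vapply(1:5, function(s) {
    pp <- generate_point_pattern("clustered", 300, c(300, 300), seed = s,
                                 n_parents = 20, sigma = 1e4)
    hopkins_index(pp, m = 30, repeats = 33, seed = s)
  }, numeric(1))
  expect_true(all(meds_cl < 2))
})

test_that("November growth stays below 8% coverage; seasons plateau as expected", {
  nov <- generate_growth_series("november", seed = 4)
  expect_true(all(nov$coverage$y <= 0.08))
  aug <- generate_growth_series("august", seed = 4)
  expect_true(max(aug$coverage$y) > 0.3)
  expect_true(aug$params$f_max >= 0.42 && aug$params$f_max <= 0.45)
  apr <- generate_growth_series("april", seed = 4)
  expect_true(apr$params$f_max >= 0.38 && apr$params$f_max <= 0.41)
  expect_error(generate_growth_series("march"), "arg")
})

test_that("noiseless growth series are exactly logistic; AC is non-decreasing", {
  g <- generate_growth_series("august", seed = 6, noise_sd = 0)
  p <- g$params
  expect_equal(g$coverage$y,
               p$f_max / (1 + exp(-p$k * (g$coverage$t - p$t0))))
  expect_true(all(diff(g$ac$y) >= 0))
  expect_true(all(diff(g$ac$y[g$ac$t >= p$t0]) > 0))
})

test_that("growth-series fits recover the generating parameters", {
  g <- generate_growth_series("august", seed = 15)
  fit <- fit_sigmoid_coverage(g$coverage)
  est <- tidy(fit)
  expect_lt(abs(est$estimate[est$term == "f_max"] - g$params$f_max), 0.05)
})
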