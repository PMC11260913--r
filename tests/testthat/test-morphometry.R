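test_that("slice-area extrapolation gives exact volumes", {
  expect_equal(cavity_volume(c(12, 20, 12), dz = 1.25), 0.055)
  expect_equal(cavity_volume(1, dz = 1.25), 0.00125)  # single voxel
  expect_error(cavity_volume(c(1, -1), 1.25), "nonnegative")
  expect_error(cavity_volume(1, 0), "positive")

  m <- digit_sphere_mask(10)
  v <- sum(m) * prod(c(1, 1, 1.25)) / 1000
  expect_lt(abs(v - 4 / 3 * pi * 10^3 / 1000) / (4 / 3 * pi * 10^3 / 1000),
            0.05)
})

test_that("surface areas of spheres and slabs match analytic oracles", {
  sp <- c(1, 1, 1.25)
  a10 <- surface_area_mask(digit_sphere_mask(10), sp)
  expect_lt(abs(a10 - 4 * pi * 100) / (4 * pi * 100), 0.10)

  slab <- slab_mask(20, 20)
  a_true <- 2 * 20 * 20 + 4 * 20 * 1.25
  a_slab <- surface_area_mask(slab, sp)
  expect_lt(abs(a_slab - a_true) / a_true, 0.15)

  single <- array(FALSE, c(9, 9, 9))
  single[5, 5, 5] <- TRUE
  expect_gt(surface_area_mask(single, sp), 0)

  # deterministic for fixed input
  expect_identical(surface_area_mask(digit_sphere_mask(6), sp),
                   surface_area_mask(digit_sphere_mask(6), sp))
})

test_that("roundness is the isoperimetric sphericity", {
  r <- 7.3
  expect_equal(roundness(4 / 3 * pi * r^3 / 1000, 4 * pi * r^2), 1)
  expect_error(roundness(0.5, 0), "surface")
  expect_error(roundness(0, 10), "volume")

  # analytic slab sphericity is well below the crack cutoff
  v_slab <- 20 * 20 * 1.25 / 1000
  a_slab <- 2 * 20 * 20 + 4 * 20 * 1.25
  expect_lt(roundness(v_slab, a_slab), 0.6)
})

test_that("digitized sphere roundness approaches 1 and cracks stay low", {
  sp <- c(1, 1, 1.25)
  psi <- vapply(c(4, 8, 16), function(r) {
    m <- digit_sphere_mask(r)
    roundness(sum(m) * prod(sp) / 1000, surface_area_mask(m, sp))
  }, numeric(1))
  expect_true(all(psi >= 0.90 & psi <= 1.10))
  dev <- abs(psi - 1)
  expect_true(all(diff(dev) <= 0.005))  # monotone toward 1 within tolerance

  slab <- slab_mask(20, 20)
  psi_slab <- roundness(sum(slab) * prod(sp) / 1000,
                        surface_area_mask(slab, sp))
  expect_lt(psi_slab, 0.6)

  # discretization pushes tiny cavities above 1
  m2 <- digit_sphere_mask(2)
  expect_gt(roundness(sum(m2) * prod(sp) / 1000, surface_area_mask(m2, sp)),
            1)
})

test_that("the two volume computations coincide exactly per cavity", {
  ph <- generate_phantom(phantom_spec(wheel_radius_mm = 30,
                                      wheel_height_mm = 30, n_eyes = 10,
                                      eye_radius = list(dist = "uniform",
                                                        min = 1.5, max = 5),
                                      seed = 23))
  res <- analyze_scan(ph$volume)
  cat <- res$catalog
  dz <- res$labels$spacing[3]
  for (i in seq_len(nrow(cat))) {
    v_slices <- cavity_volume(cat$slice_areas[[i]][, "area_mm2"], dz)
    expect_identical(v_slices, cat$volume_cm3[i])
    expect_identical(cat$volume_cm3[i],
                     cat$voxel_count[i] * prod(res$labels$spacing) / 1000)
  }
})

test_that("crack flagging separates flat voids from round eyes", {
  # a 40 x 30 x 1.25 mm planar void inside a wheel, plus one round eye
  ph <- generate_phantom(phantom_spec(wheel_radius_mm = 45,
                                      wheel_height_mm = 50,
                                      eye_centers = matrix(c(70, 48, 15), 1),
                                      eye_radii = 6,
                                      n_cracks = 1,
                                      crack_extent_mm = c(40, 30),
                                      crack_thickness_mm = 1.25,
                                      seed = 31))
  res <- analyze_scan(ph$volume)
  cat <- res$catalog
  expect_equal(nrow(cat), 2L)
  crack_row <- which.max(cat$surface_area_mm2 / cat$volume_cm3)
  eye_row <- setdiff(1:2, crack_row)
  expect_true(cat$crack_flag[crack_row])
  expect_false(cat$crack_flag[eye_row])
  expect_lt(cat$roundness[crack_row], 0.4)
  expect_gt(cat$roundness[eye_row], 0.9)
  expect_gt(cat$volume_cm3[crack_row], 1)

  expect_identical(flag_cracks(cat[0, ]), cat[0, ])
})

test_that("percentiles interpolate linearly between order statistics", {
  expect_equal(percentile(1:5, 50), 3)
  expect_equal(percentile(42, 10), 42)
  expect_equal(percentile(42, 95), 42)
  expect_equal(percentile(seq(0.1, 1, by = 0.1), 10), 0.19)
  expect_error(percentile(numeric(0), 50), "empty")
  expect_error(percentile(1:3, 101), "0, 100")
})

test_that("wheel summaries obey the ratio and eye-percent identities", {
  # total eye volume 1 cm3 against a 99 cm3 wheel
  catalog <- data.frame(label = 1L, voxel_count = 800, volume_cm3 = 1,
                        surface_area_mm2 = 500, roundness = 0.97,
                        crack_flag = FALSE)
  s <- summarize_wheel(catalog, wheel_voxel_count = 99 / 0.00125,
                       spacing = c(1, 1, 1.25))
  expect_equal(s$ratio, 1 / 99)
  expect_equal(s$eye_percent, 1.0)
  expect_equal(s$eye_percent, 100 * s$ratio / (1 + s$ratio))

  empty <- summarize_wheel(catalog[0, ], wheel_voxel_count = 1000,
                           spacing = c(1, 1, 1.25))
  expect_equal(empty$n_eyes, 0L)
  expect_equal(empty$ratio, 0)
  expect_equal(empty$eye_percent, 0)
  expect_true(is.na(empty$mean_eye_volume_cm3))
  expect_true(is.na(empty$mean_roundness))
})

test_that("eye percent is bounded by and converges to 100 * ratio", {
  ratios <- c(1e-4, 1e-3, 0.01, 0.05, 0.3, 1, 4)
  eyep <- 100 * ratios / (1 + ratios)
  expect_true(all(eyep < 100 * ratios))
  small <- ratios[ratios <= 0.01]
  rel_err <- (100 * small - 100 * small / (1 + small)) / (100 * small)
  expect_true(all(rel_err < 0.011))
})

test_that("crack-flagged cavities can be excluded from eye summaries", {
  catalog <- data.frame(label = 1:2, voxel_count = c(800, 1200),
                        volume_cm3 = c(1, 1.5),
                        surface_area_mm2 = c(500, 2500),
                        roundness = c(0.97, 0.3),
                        crack_flag = c(FALSE, TRUE))
  incl <- summarize_wheel(catalog, 1e5, c(1, 1, 1.25), include_cracks = TRUE)
  excl <- summarize_wheel(catalog, 1e5, c(1, 1, 1.25), include_cracks = FALSE)
  expect_equal(incl$n_eyes, 2L)
  expect_equal(excl$n_eyes, 1L)
  expect_equal(excl$total_eye_volume_cm3, 1)
  expect_equal(incl$n_cracks, 1L)
})
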