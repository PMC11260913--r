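test_that("density thresholding is inclusive at the boundary", {
  rho <- make_density(array(c(849, 850, 851, 1150, 0, 1.2), c(6, 1, 1)))
  m <- threshold_volume(rho, 850)
  expect_equal(as.vector(m$mask), c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))

  uni <- make_density(array(1150, c(4, 4, 3)))
  expect_true(all(threshold_volume(uni)$mask))
  expect_equal(threshold_volume(uni)$threshold_used, 850)
})

test_that("extract_wheel keeps the largest component and drops specks", {
  m <- array(FALSE, c(20, 20, 10))
  m[5:15, 5:15, 3:8] <- TRUE        # the wheel
  m[2, 2, 2] <- TRUE                # three isolated specks
  m[18, 2, 9] <- TRUE
  m[2, 18, 5] <- TRUE
  w <- extract_wheel(binary_mask(m))
  expect_equal(sum(w$mask), 11 * 11 * 6)
  expect_equal(attr(w, "dropped_voxels"), 3)
  expect_false(w$mask[2, 2, 2])

  allt <- binary_mask(array(TRUE, c(5, 5, 5)))
  expect_identical(extract_wheel(allt)$mask, allt$mask)

  expect_error(extract_wheel(binary_mask(array(FALSE, c(4, 4, 4)))),
               "no wheel")
})

test_that("equal-size largest components tie-break deterministically", {
  m <- array(FALSE, c(12, 12, 6))
  m[2:3, 2:3, 2:3] <- TRUE
  m[9:10, 9:10, 4:5] <- TRUE
  expect_warning(w <- extract_wheel(binary_mask(m)), "equal-size")
  expect_true(w$mask[2, 2, 2])     # smaller linear index wins
  expect_false(w$mask[9, 9, 4])
})

test_that("interior cavities are labeled; coalesced eyes count once", {
  one <- generate_phantom(phantom_spec(wheel_radius_mm = 20,
                                       wheel_height_mm = 20, n_eyes = 0,
                                       eye_centers = matrix(c(23, 23, 16.25),
                                                            1),
                                       eye_radii = 5))
  res <- analyze_scan(one$volume)
  expect_equal(res$labels$n_cavities, 1L)

  # two overlapping spheres merge into a single cavity
  two <- generate_phantom(phantom_spec(wheel_radius_mm = 25,
                                       wheel_height_mm = 30,
                                       eye_centers = rbind(c(24, 28, 20),
                                                           c(30, 28, 20)),
                                       eye_radii = c(4, 4),
                                       allow_overlap = TRUE))
  expect_equal(two$truth$expected_components, 1L)
  res2 <- analyze_scan(two$volume)
  expect_equal(res2$labels$n_cavities, 1L)

  # disjoint spheres are recovered one-to-one
  many <- generate_phantom(phantom_spec(wheel_radius_mm = 45,
                                        wheel_height_mm = 45, n_eyes = 25,
                                        eye_radius = list(dist = "uniform",
                                                          min = 2, max = 5),
                                        seed = 17))
  expect_equal(many$truth$expected_components, 25L)
  res3 <- analyze_scan(many$volume)
  expect_equal(res3$labels$n_cavities, 25L)
})

test_that("below-threshold voxels partition into air, cavities and specks", {
  ph <- generate_phantom(phantom_spec(wheel_radius_mm = 30,
                                      wheel_height_mm = 30, n_eyes = 8,
                                      eye_radius = list(dist = "uniform",
                                                        min = 2, max = 6),
                                      noise_sd = 25, seed = 9))
  res <- analyze_scan(ph$volume)
  lab <- res$labels
  total <- prod(dim(ph$volume$ctn))
  expect_identical(
    attr(lab, "wheel_voxels") + attr(lab, "external_air_voxels") +
      sum(attr(lab, "cavity_voxels")) + attr(lab, "discarded_voxels"),
    total)
  # every labeled voxel is below threshold
  expect_true(all(res$density$rho[lab$labels > 0L] < 850))
})

test_that("cavity count is invariant under axis permutation and flips", {
  ph <- generate_phantom(phantom_spec(wheel_radius_mm = 22,
                                      wheel_height_mm = 22, n_eyes = 6,
                                      eye_radius = list(dist = "uniform",
                                                        min = 1.5, max = 4),
                                      spacing = c(1, 1, 1), seed = 4))
  base <- analyze_scan(ph$volume)
  counts0 <- sort(attr(base$labels, "cavity_voxels"))
  arr <- ph$volume$ctn
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))) {
    v <- scan_volume(aperm(arr, perm), spacing = c(1, 1, 1))
    res <- analyze_scan(v)
    expect_equal(res$labels$n_cavities, base$labels$n_cavities)
    expect_equal(sort(attr(res$labels, "cavity_voxels")), counts0)
  }
  flipped <- scan_volume(arr[dim(arr)[1]:1, , ], spacing = c(1, 1, 1))
  expect_equal(analyze_scan(flipped)$labels$n_cavities,
               base$labels$n_cavities)
})

test_that("raising the minimum cavity volume never increases the count", {
  ph <- generate_phantom(phantom_spec(wheel_radius_mm = 30,
                                      wheel_height_mm = 30, n_eyes = 12,
                                      eye_radius = list(dist = "uniform",
                                                        min = 1.2, max = 5),
                                      seed = 3))
  dens <- density_volume(ph$volume)
  mask <- threshold_volume(dens)
  wheel <- extract_wheel(mask)
  ks <- vapply(c(0, 0.005, 0.01, 0.05, 0.2, 1),
               function(mv) label_cavities(mask, wheel,
                                           min_volume_cm3 = mv)$n_cavities,
               integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("compiled labeling matches the brute-force flood-fill oracle", {
  set.seed(101)
  for (rep in 1:30) {
    m <- random_mask(c(20L, 20L, 20L), p = runif(1, 0.5, 0.8))
    for (conn in c(6, 26)) {
      # dense random masks legitimately touch all faces; silence the
      # field-of-view warning for these synthetic cases
      wheel <- extract_wheel(m)
      fast <- suppressWarnings(label_cavities(m, wheel, connectivity = conn))
      slow <- labeling_oracle(m, connectivity = conn)
      expect_identical(canonical_partition(fast$labels),
                       canonical_partition(slow$labels))
      expect_identical(fast$n_cavities, slow$n_cavities)
    }
  }
})

test_that("oracle refuses oversize volumes and handles degenerate phases", {
  expect_error(labeling_oracle(binary_mask(array(TRUE, c(40, 4, 4)))),
               "32")
  allt <- binary_mask(array(TRUE, c(8, 8, 8)))
  expect_equal(labeling_oracle(allt)$n_cavities, 0L)
  # hollow cube: all-false interior becomes one cavity
  m <- array(TRUE, c(10, 10, 10))
  m[3:8, 3:8, 3:8] <- FALSE
  expect_equal(labeling_oracle(binary_mask(m), min_volume_cm3 = 0)$n_cavities,
               1L)
})

test_that("2d-stacked mode preserves total cavity volume", {
  ph <- generate_phantom(phantom_spec(wheel_radius_mm = 25,
                                      wheel_height_mm = 25, n_eyes = 5,
                                      eye_radius = list(dist = "uniform",
                                                        min = 2, max = 5),
                                      seed = 12))
  dens <- density_volume(ph$volume)
  mask <- threshold_volume(dens)
  wheel <- extract_wheel(mask)
  l3 <- label_cavities(mask, wheel, mode = "3d")
  l2 <- label_cavities(mask, wheel, mode = "2d-stacked")
  expect_identical(sum(attr(l2, "cavity_voxels")),
                   sum(attr(l3, "cavity_voxels")))
  expect_gte(l2$n_cavities, l3$n_cavities)
})

test_that("a wheel clipped by the field of view raises a warning", {
  m <- binary_mask(array(TRUE, c(6, 6, 6)))
  w <- extract_wheel(m)
  expect_warning(label_cavities(m, w), "field of view")
})
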