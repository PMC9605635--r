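test_that("phantom ground truth matches analytic geometry", {
  sp <- phantom_spec(
    grid_shape = c(34, 34, 34), spacing = c(1, 1, 1),
    lesions = lesion_spec(center = c(16, 16, 16), base_radius = 10,
                          hotspot_radial_fraction = 0),
    background_suv = 0.3, noise_sd = 0, seed = 11)
  ph <- make_phantom(sp)
  expect_equal(ph$truth$true_volume_mm3, 4 / 3 * pi * 1000, tolerance = 1e-12)
  # hotspot at radial fraction 0 sits at the lesion centre
  expect_equal(c(ph$truth$hotspot_x, ph$truth$hotspot_y, ph$truth$hotspot_z),
               c(16, 16, 16))
  expect_equal(ph$lesion_count, 1)
})

test_that("phantoms are deterministic and respect grid bounds", {
  sp <- two_focus_spec(seed = 5)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$grid$values, b$grid$values)
  expect_equal(a$lesion_count, 2)

  too_big <- phantom_spec(
    grid_shape = c(20, 20, 20), spacing = c(1, 1, 1),
    lesions = lesion_spec(center = c(10, 10, 10), base_radius = 9),
    seed = 1)
  expect_error(make_phantom(too_big), "margin")
})

test_that("voxelized sphere volume converges to the analytic volume", {
  errs <- vapply(c(2, 1, 0.5), function(h) {
    n <- ceiling(34 / h)
    sp <- phantom_spec(
      grid_shape = rep(n, 3), spacing = rep(h, 3),
      lesions = lesion_spec(center = c(15.7, 15.3, 15.5), base_radius = 10),
      background_suv = 0.3, noise_sd = 0, seed = 3)
    ph <- make_phantom(sp)
    v <- sum(ph$grid$values > 1.65) * h^3
    abs(v / (4 / 3 * pi * 1000) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.005)
})

test_that("bridged phantoms enforce the intensity contract", {
  sp <- two_focus_spec(seed = 2, noise_sd = 0)
  expect_error(make_bridged_phantom(sp, bridge_suv = 0.3), "strictly between")
  expect_error(make_bridged_phantom(sp, bridge_suv = 3.2), "strictly between")

  one <- phantom_spec(grid_shape = c(34, 34, 34), spacing = c(1, 1, 1),
                      lesions = lesion_spec(center = c(16, 16, 16),
                                            base_radius = 8), seed = 1)
  expect_error(make_bridged_phantom(one, 0.8), "two lesions")

  # corridor connects the foci at a low threshold, not at a high one
  ph <- make_bridged_phantom(sp, bridge_suv = 0.8)
  high <- segment_threshold(ph$grid, list(fraction_of_max = 0.4))
  expect_equal(length(high$N), 2)
  low <- segment_threshold(ph$grid, list(absolute = 0.6), min_voxels = 10)
  expect_equal(length(low$N), 1)
})
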