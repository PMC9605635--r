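test_that("sphericity closed forms: sphere is 1, cube is ~0.806", {
  r <- 10
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1, tolerance = 1e-12)
  a <- 7
  expect_equal(sphericity(a^3, 6 * a^2), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_error(sphericity(0, 10), "positive")
})

test_that("triangulated surface area tracks the analytic sphere", {
  m <- sphere_mask(10, 1)
  s1 <- surface_area(m, c(1, 1, 1))
  expect_equal(s1, 4 * pi * 100, tolerance = 0.03)

  m05 <- sphere_mask(10, 0.5)
  s05 <- surface_area(m05, c(0.5, 0.5, 0.5))
  expect_equal(s05, 4 * pi * 100, tolerance = 0.03)
  # refinement consistency
  expect_equal(s1 / s05, 1, tolerance = 0.03)

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  s <- surface_area(single, c(1, 1, 1))
  expect_true(is.finite(s) && s > 0)
  expect_error(surface_area(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("maximum diameter is the farthest surface-voxel pair", {
  m <- array(FALSE, c(6, 7, 3))
  m[1, 1, 1] <- TRUE
  m[4, 5, 1] <- TRUE # (3, 4, 0) mm away: a 3-4-5 triangle
  expect_equal(max_diameter(m, c(1, 1, 1)), 5)

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(max_diameter(single, c(1, 1, 1)), 0)

  sph <- sphere_mask(10, 1)
  expect_equal(max_diameter(sph, c(1, 1, 1)), 20, tolerance = sqrt(3) / 20)
})

test_that("centroid is the unweighted mean of active voxel centres", {
  m <- array(FALSE, c(5, 5, 5)); m[2, 3, 4] <- TRUE
  expect_equal(lesion_centroid(m, c(1, 1, 1)), c(1, 2, 3))
  m[4, 3, 2] <- TRUE
  expect_equal(lesion_centroid(m, c(1, 1, 1)), c(2, 2, 2))

  sph <- sphere_mask(9, 1)
  ctr_true <- rep((dim(sph)[1] - 1) / 2, 3)
  expect_equal(lesion_centroid(sph, c(1, 1, 1)), ctr_true,
               tolerance = 0.5, ignore_attr = TRUE)
})

test_that("centroid distances and their normalization follow the closed forms", {
  ctr <- c(10, 10, 10)
  cd <- centroid_distances(ctr, ctr + c(3, 4, 0), ctr)
  expect_equal(cd$smcd, 5)
  expect_equal(cd$spcd, 0)

  ns <- normalized_scd(0, 4 / 3 * pi * 1000)
  expect_equal(ns$msr, 10)
  expect_equal(ns$nspcd, 0)
  expect_equal(ns$nspcd_class, "central")
  expect_equal(normalized_scd(7, 4 / 3 * pi * 1000)$nspcd, 0.7)
  expect_equal(normalized_scd(7, 4 / 3 * pi * 1000)$nspcd_class, "peripheral")
  expect_error(normalized_scd(1, 0), "positive")
})

test_that("spherical rim width is the difference of equivalent radii", {
  v10 <- 4 / 3 * pi * 1000
  v5 <- 4 / 3 * pi * 125
  expect_equal(rim_width(v10, v5), 5, tolerance = 1e-12)
  expect_equal(rim_width(v10, 0), 10, tolerance = 1e-12)
  expect_error(rim_width(v5, v10), "exceed")

  # voxelized 5-10 mm shell at 0.5 mm spacing
  g <- sphere_grid(r = 10, h = 0.5, core_r = 5)
  ls <- segment_threshold(g, list(fraction_of_max = 0.5))
  vol <- lesion_volumes(ls, 1)
  expect_equal(rim_width(vol$volume_total, vol$volume_inner), 5,
               tolerance = 0.05)
  expect_equal(vol$volume_inner, v5, tolerance = 0.05)
})

test_that("geometric features are intensity-scale invariant and translation invariant", {
  ph <- make_phantom(phantom_spec(
    grid_shape = c(44, 44, 44), spacing = c(1, 1, 1),
    lesions = lesion_spec(center = c(21, 21, 21), base_radius = 9,
                          hotspot_radial_fraction = 0.6, hotspot_suv = 5),
    background_suv = 0.3, noise_sd = 0, seed = 9))
  ls <- segment_threshold(ph$grid, list(fraction_of_max = 0.4))
  f1 <- geom_features(ph$grid, ls)

  g2 <- ph$grid; g2$values <- g2$values * 2.5
  ls2 <- segment_threshold(g2, list(fraction_of_max = 0.4))
  f2 <- geom_features(g2, ls2)
  expect_equal(f1, f2, tolerance = 1e-12)

  # rigid translation of the world frame leaves all distances unchanged
  g3 <- ph$grid; g3$origin <- c(-40, 12.5, 7)
  ls3 <- segment_threshold(g3, list(fraction_of_max = 0.4))
  f3 <- geom_features(g3, ls3)
  expect_equal(f3$smcd_mm, f1$smcd_mm, tolerance = 1e-9)
  expect_equal(f3$spcd_mm, f1$spcd_mm, tolerance = 1e-9)
  expect_equal(f3$sphericity, f1$sphericity, tolerance = 1e-12)
})

test_that("sphericity decreases along the bumpiness family", {
  sph <- vapply(c(0, 0.15, 0.3), function(b) {
    ph <- make_phantom(phantom_spec(
      grid_shape = c(44, 44, 44), spacing = c(1, 1, 1),
      lesions = lesion_spec(center = c(21, 21, 21), base_radius = 9,
                            bumpiness = b),
      background_suv = 0.3, noise_sd = 0, seed = 6))
    ls <- segment_threshold(ph$grid, list(fraction_of_max = 0.5))
    geom_features(ph$grid, ls)$sphericity
  }, numeric(1))
  expect_true(all(diff(sph) < 0))
  expect_lt(sph[1], 1.02)
  expect_gt(sph[1], 0.98)
})

test_that("hotspot radial position is recovered by nSpCD", {
  ph <- make_phantom(phantom_spec(
    grid_shape = c(44, 44, 44), spacing = c(1, 1, 1),
    lesions = lesion_spec(center = c(21, 21, 21), base_radius = 12,
                          hotspot_radial_fraction = 0.5,
                          hotspot_suv = 4.5, rim_suv = 3),
    background_suv = 0.3, noise_sd = 0, seed = 14))
  ls <- segment_threshold(ph$grid, list(absolute = 1.65))
  f <- geom_features(ph$grid, ls)
  expect_equal(f$nspcd, 0.5, tolerance = 0.1)
})
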