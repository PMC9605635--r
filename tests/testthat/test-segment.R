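test_that("threshold segmentation recovers a uniform sphere", {
  g <- sphere_grid(r = 10, h = 1)
  ls <- segment_threshold(g, list(fraction_of_max = 0.5))
  expect_equal(length(ls$N), 1)
  expect_equal(ls$N[1] * voxel_volume(g), 4 / 3 * pi * 1000,
               tolerance = 0.05)
  expect_error(segment_threshold(g, list(absolute = 10)), "threshold")
})

test_that("enclosed hypointense cores become the inner (necrotic) mask", {
  g <- sphere_grid(r = 10, h = 1, core_r = 5)
  ls <- segment_threshold(g, list(fraction_of_max = 0.5))
  expect_equal(length(ls$N), 1)
  inner_vol <- ls$N_inner[1] * voxel_volume(g)
  expect_equal(inner_vol, 4 / 3 * pi * 125, tolerance = 0.10)
  # active and inner are disjoint and the filled sum is bounded
  expect_equal(sum(ls$label_map > 0 & ls$inner_map > 0), 0)
  expect_lte(sum(ls$N + ls$N_inner), length(g$values))
})

test_that("foreground shrinks monotonically as the threshold rises", {
  ph <- make_phantom(two_focus_spec(seed = 13, noise_sd = 0.1))
  sizes <- vapply(seq(0.3, 0.9, by = 0.1), function(f) {
    ls <- segment_threshold(ph$grid, list(fraction_of_max = f),
                            min_voxels = 1)
    sum(ls$N)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("fraction-of-max segmentation is invariant to intensity rescaling", {
  ph <- make_phantom(two_focus_spec(seed = 21, noise_sd = 0))
  ls1 <- segment_threshold(ph$grid, list(fraction_of_max = 0.4))
  g2 <- ph$grid
  g2$values <- g2$values * 3.7
  ls2 <- segment_threshold(g2, list(fraction_of_max = 0.4))
  expect_identical(ls1$label_map, ls2$label_map)
})

test_that("multilesionality follows the bridged/unbridged construction", {
  single <- make_phantom(phantom_spec(
    grid_shape = c(34, 34, 34), spacing = c(1, 1, 1),
    lesions = lesion_spec(center = c(16, 16, 16), base_radius = 8),
    background_suv = 0.3, noise_sd = 0.02, seed = 1))
  expect_equal(classify_multilesionality(single$grid)$classification,
               "unifocal")

  apart <- make_phantom(two_focus_spec(seed = 2))
  expect_equal(classify_multilesionality(apart$grid)$classification,
               "multicentric")

  bridged <- make_bridged_phantom(two_focus_spec(seed = 3), bridge_suv = 0.8)
  cls <- classify_multilesionality(bridged$grid)
  expect_equal(cls$classification, "multifocal")
  expect_true(cls$multilesional)
})

test_that("the measurement lesion is the largest filled volume, ties to lowest label", {
  ph <- make_phantom(two_focus_spec(seed = 4, noise_sd = 0))
  ls <- segment_threshold(ph$grid, list(fraction_of_max = 0.4))
  sel <- select_measurement_lesion(ls)
  expect_equal(sel, which.max((ls$N + ls$N_inner)))
  expect_equal(sel, 1L) # labels are size-ordered

  tie <- fake_lesion_set(N = c(50L, 50L))
  expect_equal(select_measurement_lesion(tie), 1L)
  # inner voxels count towards the filled volume
  necro <- fake_lesion_set(N = c(50L, 40L), N_inner = c(0L, 30L))
  expect_equal(select_measurement_lesion(necro), 2L)
  expect_error(select_measurement_lesion(fake_lesion_set(integer(0))),
               "empty")
})
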