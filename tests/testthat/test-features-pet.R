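test_that("SUV statistics use the population convention", {
  g <- sphere_grid(r = 5, h = 1, inside = 2.5)
  mask <- g$values > 1
  st <- suv_statistics(g, mask)
  expect_equal(st$suv_max, 2.5)
  expect_equal(st$suv_mean, 2.5)
  expect_equal(st$sd, 0)

  # two voxels {2, 4}: population SD is 1
  vals <- array(0, c(3, 3, 3))
  vals[1, 1, 1] <- 2; vals[3, 3, 3] <- 4
  g2 <- voxel_grid(vals, c(1, 1, 1))
  m2 <- vals > 0
  st2 <- suv_statistics(g2, m2)
  expect_equal(st2$suv_max, 4)
  expect_equal(st2$suv_mean, 3)
  expect_equal(st2$sd, 1)
  expect_equal(st2$suv_max_location, c(2, 2, 2))

  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  expect_equal(suv_statistics(g2, m1)$sd, 0)
  expect_error(suv_statistics(g2, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("SUVpeak equals the 27-voxel average and its brute-force oracle", {
  # one bright voxel of 27 amid zeros averages to exactly 1
  vals <- array(0, c(5, 5, 5))
  vals[3, 3, 3] <- 27
  g <- voxel_grid(vals, c(1, 1, 1))
  pk <- suv_peak(g, array(TRUE, c(5, 5, 5)))
  expect_equal(pk$suv_peak, 1)
  # all 27 voxels around the bright one tie at 1; the documented
  # tie-break picks the first in array order, the corner at (1,1,1)
  expect_equal(pk$suv_peak_location, c(1, 1, 1))
  m_only <- array(FALSE, c(5, 5, 5)); m_only[3, 3, 3] <- TRUE
  expect_equal(suv_peak(g, m_only)$suv_peak_location, c(2, 2, 2))

  set.seed(17)
  for (i in 1:30) {
    a <- array(stats::runif(729), c(9, 9, 9))
    gi <- voxel_grid(a, c(1, 1, 1))
    got <- suv_peak(gi, array(TRUE, c(9, 9, 9)))
    want <- brute_force_peak(a)
    expect_lt(abs(got$suv_peak - want$peak) / want$peak, 1e-10)
  }
})

test_that("SUVpeak never exceeds SUVmax and is translation equivariant", {
  set.seed(31)
  for (i in 1:10) {
    a <- array(stats::rexp(12^3), c(12, 12, 12))
    g <- voxel_grid(a, c(1, 1, 1))
    mask <- array(TRUE, dim(a))
    expect_lte(suv_peak(g, mask)$suv_peak, suv_statistics(g, mask)$suv_max)
  }

  base <- make_phantom(phantom_spec(
    grid_shape = c(40, 40, 40), spacing = c(1, 1, 1),
    lesions = lesion_spec(center = c(16, 16, 16), base_radius = 7,
                          hotspot_radial_fraction = 0.5, hotspot_suv = 5),
    background_suv = 0.3, noise_sd = 0, seed = 8))
  shifted <- base$grid
  shifted$values <- array(0.3, dim(base$grid$values))
  shifted$values[4:40, 3:40, 2:40] <-
    base$grid$values[1:37, 1:38, 1:39]
  mask_b <- base$grid$values > 1.5
  mask_s <- shifted$values > 1.5
  pb <- suv_peak(base$grid, mask_b)
  ps <- suv_peak(shifted, mask_s)
  expect_equal(ps$suv_peak, pb$suv_peak, tolerance = 1e-12)
  expect_equal(ps$suv_peak_location, pb$suv_peak_location + c(3, 2, 1))
})

test_that("COV classification and scale invariance behave as specified", {
  expect_equal(suv_cov(0, 1.5)$cov, 0)
  expect_equal(suv_cov(0, 1.5)$heterogeneity, "homogeneous")
  # COV exactly at the 0.30 cut is heterogeneous
  expect_equal(suv_cov(0.45, 1.5)$heterogeneity, "heterogeneous")
  expect_equal(suv_cov(0.45, 1.5)$cov, 0.30)
  expect_error(suv_cov(0.1, 0), "positive")

  set.seed(5)
  v <- stats::rlnorm(5000, 0, 0.4)
  for (c_ in c(0.5, 2, 10)) {
    m <- mean(c_ * v)
    s <- sqrt(mean((c_ * v - m)^2))
    expect_equal(suv_cov(s, m)$cov,
                 suv_cov(sqrt(mean((v - mean(v))^2)), mean(v))$cov,
                 tolerance = 1e-12)
  }
})

test_that("lognormal uptake with sigma/mu = 0.5 yields COV near 0.5", {
  g <- sphere_grid(r = 10, h = 1)
  mask <- g$values > 1
  sdlog <- sqrt(log(1.25)) # cv^2 = exp(sdlog^2) - 1 = 0.25
  set.seed(12)
  g$values[mask] <- stats::rlnorm(sum(mask), meanlog = 1, sdlog = sdlog)
  st <- suv_statistics(g, mask)
  cv <- suv_cov(st$sd, st$suv_mean)
  expect_equal(cv$cov, 0.5, tolerance = 0.05)
})

test_that("MTV and TLA follow their defining products", {
  ls <- fake_lesion_set(N = 1000L, vv = 8)
  mt <- mtv_tla(ls, 1, suv_mean = 1.37)
  expect_equal(mt$mtv, 8)
  expect_equal(mt$tla, 1.37 * 8)
})
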