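test_that("feature correlation flags exact and null relationships", {
  set.seed(3)
  d <- tibble::tibble(pet_v = stats::runif(1000, 1, 5))
  d$mri_v <- 2 * d$pet_v
  d$mri_null <- stats::rnorm(1000)
  d$mri_const <- 1
  res <- correlate_features(d, "pet_v", c("mri_v", "mri_null", "mri_const"))
  expect_equal(res$r[res$mri_var == "mri_v"], 1, tolerance = 1e-12)
  expect_true(res$robust[res$mri_var == "mri_v"])
  expect_lt(abs(res$r[res$mri_var == "mri_null"]), 0.1)
  expect_false(res$robust[res$mri_var == "mri_null"])
  expect_true(is.na(res$r[res$mri_var == "mri_const"]))
})

test_that("a noisy linear PET-MRI volume link is flagged robust", {
  set.seed(8)
  d <- tibble::tibble(pet_volume = stats::runif(54, 10, 80))
  d$mri_volume <- 0.61 * d$pet_volume + stats::rnorm(54, 0, 3)
  res <- correlate_features(d, "pet_volume", "mri_volume")
  expect_true(res$robust)
})

test_that("median dichotomization splits with ties to the low group", {
  d <- tibble::tibble(
    os_months = c(1, 2, 5, 5, 8, 11), os_event = TRUE,
    pfs_months = c(1, 2, 5, 5, 8, 11), pfs_event = TRUE,
    feat = c(10, 11, 12, 20, 21, 22),
    flat = 1)
  res <- dichotomize_and_test(d, "os", c("feat", "flat"))
  expect_equal(res$n_low[1], 4) # both 5s fall in the <= median group
  expect_equal(res$n_high[1], 2)
  expect_true(is.na(res$p[res$feature == "flat"]))
  expect_false(is.na(res$normality_p[1]))

  set.seed(2)
  shifted <- tibble::tibble(
    os_months = c(stats::runif(27, 1, 5), stats::runif(27, 6, 20)),
    os_event = TRUE, pfs_months = 1, pfs_event = TRUE,
    suv = c(stats::rnorm(27, 4.2, 1), stats::rnorm(27, 3.0, 1)))
  res2 <- dichotomize_and_test(shifted, "os", "suv")
  expect_lt(res2$p, 0.05)
})

test_that("ROC follows the hand-enumerated toy curve and the U-statistic oracle", {
  toy <- tibble::tibble(x = c(1, 2, 3, 4),
                        short = c(FALSE, FALSE, TRUE, TRUE))
  r <- roc_cutoff(toy, "short", "x")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_gt(r$cutoff, 2)
  expect_lt(r$cutoff, 3)

  set.seed(23)
  for (i in 1:30) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    d <- tibble::tibble(
      x = c(sample(1:6, n1, TRUE) + stats::rnorm(n1, 1, 0.5),
            sample(1:6, n0, TRUE) * 1.0),
      cls = rep(c(TRUE, FALSE), c(n1, n0)))
    got <- roc_cutoff(d, "cls", "x")$auc
    want <- mann_whitney_auc(d$x[d$cls], d$x[!d$cls])
    expect_equal(got, want, tolerance = 1e-12)
  }

  set.seed(4)
  null_d <- tibble::tibble(x = stats::rnorm(4000),
                           cls = rep(c(TRUE, FALSE), 2000))
  expect_equal(roc_cutoff(null_d, "cls", "x")$auc, 0.5, tolerance = 0.05)
  expect_error(roc_cutoff(tibble::tibble(x = 1:3, cls = TRUE), "cls", "x"),
               "non-empty")
})

test_that("Kaplan-Meier with no censoring equals the empirical survival", {
  set.seed(6)
  d <- tibble::tibble(
    os_months = c(stats::rexp(25, 1 / 10), stats::rexp(25, 1 / 4)),
    os_event = TRUE,
    pfs_months = 1, pfs_event = TRUE,
    grp = rep(c(FALSE, TRUE), each = 25))
  km <- km_logrank(d, "os", "grp")
  for (g in c("FALSE", "TRUE")) {
    cv <- km$curves[km$curves$group == g, ]
    times <- d$os_months[d$grp == as.logical(g)]
    emp <- vapply(cv$time, function(t) mean(times > t), numeric(1))
    expect_equal(cv$surv, emp, tolerance = 1e-12)
  }
  expect_true(km$logrank_p >= 0 && km$logrank_p <= 1)
  expect_error(km_logrank(dplyr::mutate(d, os_event = FALSE), "os", "grp"),
               "event")
})

test_that("log-rank detects a simulated group hazard ratio", {
  hits <- 0
  for (i in 1:20) {
    cohort <- simulate_cohort(cohort_sim_spec(
      n = 300, hr_age_per_year = 1, hr_stupp_incomplete = 1,
      hr_multilesion = 2.2, hr_sphericity_per_tenth = 1,
      censor_rate = 0.1, seed = 500 + i))
    km <- km_logrank(cohort, "os", "multilesional")
    if (km$logrank_p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("Cox screening reports HRs on the stated scales", {
  cohort <- simulate_cohort(cohort_sim_spec(n = 800, seed = 77))
  res <- cox_models(cohort, "os",
                    univariate = c("age", "sphericity"),
                    multivariate = c("age", "stupp_incomplete",
                                     "multilesional", "sphericity"))
  expect_s3_class(res, "cox_screen")
  expect_true(all(res$converged))
  expect_true(all(res$ci_low <= res$hr & res$hr <= res$ci_high))
  expect_true(all(res$p >= 0 & res$p <= 1))
  # sphericity is reported per tenth of increase
  sph <- res[res$variable == "sphericity" & res$analysis == "univariate", ]
  expect_equal(sph$scale_note, "per tenth")
  raw <- survival::coxph(
    survival::Surv(os_months, os_event) ~ sphericity, data = cohort,
    ties = "efron")
  expect_equal(sph$hr, exp(0.1 * unname(coef(raw))), tolerance = 1e-6)

  # multivariate recovery of the generating HRs at moderate n
  mv <- res[res$analysis == "multivariate", ]
  expect_equal(mv$hr[mv$variable == "stupp_incomplete"], 2.813,
               tolerance = 0.25)
  expect_equal(mv$hr[mv$variable == "age"], 1.044, tolerance = 0.03)
})

test_that("null covariates give nominal Cox CI coverage", {
  cover <- 0
  for (i in 1:40) {
    cohort <- simulate_cohort(cohort_sim_spec(
      n = 300, hr_age_per_year = 1, hr_stupp_incomplete = 1,
      hr_multilesion = 1, hr_sphericity_per_tenth = 1,
      censor_rate = 0.1, seed = 9000 + i))
    res <- cox_models(cohort, "os", univariate = "multilesional")
    if (res$ci_low <= 1 && 1 <= res$ci_high) cover <- cover + 1
  }
  expect_gte(cover, 33) # ~95% nominal; allow binomial noise
})
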