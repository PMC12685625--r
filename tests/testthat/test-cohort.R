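test_that("with no noise, B1 = 1 and no effects, ΔNWU is the intercept", {
  cfg <- cohort_sim_config(n_patients = 50L, intercept = 3, coef_baseline = 1,
                           coef_ivt = 0, coef_etici = 0,
                           coef_covariates = list(age = 0, sex_male = 0,
                                                  nihss = 0, aspects = 0,
                                                  onset = 0),
                           residual_sd = 0, seed = 2L)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$cohort$nwu_24h - sim$cohort$nwu_bl, rep(3, 50))
  expect_equal(sim$cohort$nwu_1wk - sim$cohort$nwu_bl, rep(3, 50))
})

test_that("an injected reperfusion effect is recovered by OLS at scale", {
  cfg <- cohort_sim_config(n_patients = 5000L, coef_etici = -5,
                           residual_sd = 7, seed = 1L)
  sim <- simulate_cohort(cfg)
  fit <- fit_delta_model(sim$cohort, "24h", "etici2b", adjusted = TRUE)
  expect_equal(exposure_row(fit)$estimate, -5, tolerance = 0.5 / 5)
})

test_that("baseline NWU and eTICI marginals match the target distributions", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 20000L, seed = 12L))
  expect_equal(median(sim$cohort$nwu_bl), 4.3, tolerance = 0.15 / 4.3)
  expect_true(all(sim$cohort$nwu_bl > 0))
  p2b <- mean(dichotomize_etici(sim$cohort$etici, "2B"))
  p2c <- mean(dichotomize_etici(sim$cohort$etici, "2C"))
  # binomial 99.9% bounds at n = 20000
  expect_lt(abs(p2b - 0.83), 3.3 * sqrt(0.83 * 0.17 / 20000))
  expect_lt(abs(p2c - 0.57), 3.3 * sqrt(0.57 * 0.43 / 20000))
  expect_lt(abs(mean(sim$cohort$ivt) - 0.59), 3.3 * sqrt(0.59 * 0.41 / 20000))
})

test_that("the cohort generator is seed-deterministic", {
  a <- simulate_cohort(cohort_sim_config(n_patients = 100L, seed = 9L))
  b <- simulate_cohort(cohort_sim_config(n_patients = 100L, seed = 9L))
  expect_identical(a$cohort, b$cohort)
})

test_that("inconsistent configs are rejected", {
  expect_error(cohort_sim_config(p_etici2c = 0.9, p_etici2b = 0.8), "exceed")
  expect_error(cohort_sim_config(n_patients = 1), "n_patients")
  expect_error(cohort_sim_config(residual_sd = -1), "residual_sd")
  expect_error(cohort_sim_config(p_ivt = 1.2), "probabilities")
})

test_that("missingness injection is MCAR at the requested rate", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 115L, seed = 4L))
  expect_identical(inject_missingness(sim$cohort, 0), sim$cohort)
  expect_equal(sum(is.na(sim$cohort)), 0)

  miss <- inject_missingness(sim$cohort, 0.2, seed = 3L)
  n_na <- sum(is.na(miss))
  # binomial 99% bounds around 0.2 * 115 * 5
  bounds <- qbinom(c(0.005, 0.995), 115 * 5, 0.2)
  expect_gte(n_na, bounds[1])
  expect_lte(n_na, bounds[2])
  # outcome and identifier columns are never deleted
  expect_false(anyNA(miss$subject_id))
  expect_false(anyNA(miss$nwu_24h))
  expect_false(anyNA(miss$nwu_1wk))

  expect_error(inject_missingness(sim$cohort, 0.2, mechanism = "MAR"), "MCAR")
  expect_error(inject_missingness(sim$cohort, 1), "rate")
})
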