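make_fake_result <- function(estimates, ses, df = 100) {
  structure(data.frame(term = names(estimates), estimate = unname(estimates),
                       se = unname(ses),
                       ci_lo = unname(estimates - 1.96 * ses),
                       ci_hi = unname(estimates + 1.96 * ses),
                       p = NA_real_),
            class = c("nwu_regression", "data.frame"),
            n = df + 2, df = df, label = "fake", exposure = "x")
}

test_that("a complete table yields m identical copies", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 60L, seed = 2L))
  imps <- mice_impute(sim$cohort, m = 4, iterations = 3, seed = 1L)
  expect_length(imps$imputations, 4)
  for (d in imps$imputations) expect_identical(d, sim$cohort)
})

test_that("imputation is seed-deterministic, fills every cell and preserves observed data", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 150L, seed = 3L))
  miss <- inject_missingness(sim$cohort, 0.25, seed = 5L)
  a <- mice_impute(miss, m = 3, iterations = 4, seed = 9L)
  b <- mice_impute(miss, m = 3, iterations = 4, seed = 9L)
  expect_identical(a$imputations, b$imputations)
  for (d in a$imputations) {
    expect_equal(sum(is.na(d)), 0)
    obs <- !is.na(miss$age)
    expect_identical(d$age[obs], miss$age[obs])
    obs <- !is.na(miss$sex)
    expect_identical(d$sex[obs], miss$sex[obs])
    # binary column imputed into valid labels
    expect_true(all(d$sex %in% c("male", "female")))
  }
})

test_that("an entirely missing column is rejected", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 30L, seed = 4L))
  sim$cohort$age <- NA_real_
  expect_error(mice_impute(sim$cohort, m = 2, iterations = 2), "entirely missing")
})

test_that("Rubin pooling reproduces the hand-computed two-imputation case", {
  r1 <- make_fake_result(c(`(Intercept)` = 0, x = 1), c(`(Intercept)` = 0, x = 0))
  r2 <- make_fake_result(c(`(Intercept)` = 0, x = 3), c(`(Intercept)` = 0, x = 0))
  pooled <- pool_rubin(list(r1, r2))
  i <- pooled$term == "x"
  expect_equal(pooled$estimate[i], 2)
  # total variance = 0 + (1 + 1/2) * var(c(1, 3)) = 1.5 * 2 = 3
  expect_equal(pooled$se[i]^2, 3)
})

test_that("pooling degenerates to the single result when imputations agree", {
  r <- make_fake_result(c(`(Intercept)` = 0.5, x = -2), c(`(Intercept)` = 0.2, x = 0.4))
  pooled <- pool_rubin(list(r, r, r))
  expect_equal(pooled$estimate, r$estimate)
  expect_equal(pooled$se, r$se)
  expect_equal(pooled$ci_lo, r$estimate - qt(0.975, 100) * r$se)
  expect_error(pool_rubin(list(r)), "m >= 2")
  r_bad <- make_fake_result(c(`(Intercept)` = 0, y = 1), c(`(Intercept)` = 1, y = 1))
  expect_error(pool_rubin(list(r, r_bad)), "term sets differ")
})

test_that("pooled SE never falls below the mean within-imputation SE", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 200L, seed = 6L))
  miss <- inject_missingness(sim$cohort, 0.2, seed = 7L)
  imps <- mice_impute(miss, m = 5, iterations = 5, seed = 8L)
  fits <- lapply(imps$imputations, fit_delta_model, interval = "24h",
                 exposure = "etici2b", adjusted = TRUE)
  pooled <- pool_rubin(fits)
  ubar <- rowMeans(sapply(fits, function(f) f$se^2))
  expect_true(all(pooled$se^2 >= ubar - 1e-12))
})
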