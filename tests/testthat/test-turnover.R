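test_that("growth rate k is the natural-log slope between two weights", {
  expect_equal(growth_rate_k(0.7, 0.7 * exp(1), 1), 1.0)
  expect_equal(growth_rate_k(0.81, 3.38, 28), 0.0510, tolerance = 1e-3)
  expect_equal(growth_rate_k(0.44, 3.38, 35), 0.0583, tolerance = 1e-3)
  expect_error(growth_rate_k(0, 1, 10), "> 0")
  expect_error(growth_rate_k(1, 2, 0), "> 0")
})

test_that("the incorporation model evaluates exactly", {
  expect_equal(predict_d15n(8.53, 14.31, 0.05, 0.02, 0), 8.53)
  expect_equal(predict_d15n(8.53, 14.31, 0, 0, c(0, 5, 500)), rep(8.53, 3))
  expect_equal(predict_d15n(8.53, 14.31, 0.051, 0.033, 14),
               14.31 - 5.78 * exp(-1.176), tolerance = 1e-9)
  expect_equal(predict_d15n(8.53, 14.31, 0.051, 0.033, 14), 12.53,
               tolerance = 5e-3)
  expect_error(predict_d15n(8, 14, -0.1, 0.05, 1), ">= 0")
})

test_that("half-time and contributions reproduce the printed treatment values", {
  expect_equal(half_time(0.051, 0.033), 8.25, tolerance = 1e-2)
  expect_equal(round(half_time(0.051, 0.033), 1), 8.3)
  expect_equal(round(half_time(0.057, 0.018), 1), 9.2)
  expect_equal(round(half_time(0.061, 0.008), 1), 10.0)
  expect_equal(half_time(log(2), 0), 1.0)
  expect_error(half_time(0, 0), "> 0")

  expect_equal(round(unname(contribution_split(0.061, 0.008))), c(88, 12))
  expect_equal(round(unname(contribution_split(0.051, 0.033))), c(61, 39))
  expect_equal(round(unname(contribution_split(0.057, 0.018))), c(76, 24))
  expect_equal(unname(contribution_split(0.4, 0.4)), c(50, 50))
  expect_error(contribution_split(0, 0), "> 0")
})

test_that("contributions always sum to exactly 100 and t50 decreases in both rates", {
  set.seed(7)
  for (i in 1:100) {
    k <- runif(1, 0.001, 0.2); m <- runif(1, 0, 0.2)
    cs <- contribution_split(k, m)
    expect_equal(sum(cs), 100, tolerance = 1e-12)
    expect_true(all(cs >= 0 & cs <= 100))
    eps <- 1e-6
    expect_lt(half_time(k + eps, m), half_time(k, m))
    expect_lt(half_time(k, m + eps), half_time(k, m))
  }
})

test_that("the fitted m equals the grid-search SSE minimiser on noisy series", {
  for (seed in 1:6) {
    m_true <- c(0.033, 0.018, 0.008, 0.05, 0.001, 0.1)[seed]
    tr <- treatment_config("x", base_k = 0.055, true_m = m_true)
    sim <- sim_config(sampling_days = c(0, 7, 9, 14, 21, 28, 35),
                      d15n_noise_sd = 0.25)
    ser <- simulate_isotopes(tr, sim, seed = 100 + seed)
    fit <- fit_turnover(ser, k = 0.055)
    dat <- ser[ser$day >= 7, ]
    m_grid <- grid_search_m(dat$day, dat$d15n, k = 0.055, c0 = 8.53, cn = 14.31)
    expect_lt(abs(fit$m - m_grid), 2e-5)
  }
})

test_that("m is constrained non-negative and boundary solutions are flagged", {
  # true m = 0 plus noise: roughly half of unconstrained fits would be
  # negative; the constrained fit must sit at 0 with the flag set
  tr <- treatment_config("x", base_k = 0.06, true_m = 0)
  sim <- sim_config(sampling_days = c(0, 7, 9, 14, 21, 28, 35),
                    d15n_noise_sd = 0.3)
  hits <- 0
  for (seed in 1:10) {
    fit <- fit_turnover(simulate_isotopes(tr, sim, seed = seed), k = 0.06)
    expect_gte(fit$m, 0)
    if (fit$m == 0) {
      expect_true(fit$boundary)
      hits <- hits + 1
    }
  }
  expect_gt(hits, 0)
})

test_that("the asymptote can be co-estimated", {
  tr <- treatment_config("x", base_k = 0.051, true_m = 0.033)
  ser <- simulate_isotopes(tr, zero_noise_sim(
    sampling_days = c(0, 7, 9, 14, 21, 28, 35)), seed = 1)
  fit <- fit_turnover(ser, k = 0.051, estimate_cn = TRUE)
  expect_true(fit$cn_estimated)
  expect_equal(fit$cn, 14.31, tolerance = 1e-4)
  expect_equal(fit$m, 0.033, tolerance = 1e-4)
})

test_that("degenerate series are rejected with informative errors", {
  expect_error(fit_turnover(isotope_series(c(7, 7, 7, 14), c(9, 9.1, 9.2, 10),
                                           c0 = 8.53, cn = 14.31), k = 0.05),
               "3 distinct time points")
  ser <- isotope_series(c(7, 14, 21), c(10, 11, 12), c0 = 8.53)
  expect_error(fit_turnover(ser, k = 0.05), "`cn` is required")
})

test_that("turnover_fit methods are mutually consistent", {
  tr <- treatment_config("x", base_k = 0.051, true_m = 0.033)
  sim <- sim_config(sampling_days = c(0, 7, 9, 14, 21, 28, 35),
                    d15n_noise_sd = 0.2)
  ser <- simulate_isotopes(tr, sim, seed = 3)
  fit <- fit_turnover(ser, k = 0.051)
  expect_s3_class(fit, "turnover_fit")
  expect_named(coef(fit), c("k", "m"))
  expect_equal(fit$t50, log(2) / (fit$k + fit$m), tolerance = 1e-12)
  expect_equal(fit$k_contribution_pct + fit$m_contribution_pct, 100)
  expect_equal(sum(residuals(fit)^2), fit$sse, tolerance = 1e-10)
  expect_equal(fitted(fit), predict(fit), tolerance = 1e-12)
  expect_equal(predict(fit, data.frame(day = 0)), fit$c0)
  expect_output(print(fit), "t50")
  expect_output(print(summary(fit)), "residual SSE")
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "isotope_series")
})

test_that("series decomposition separates growth-only from full incorporation", {
  tr <- treatment_config("x", base_k = 0.051, true_m = 0.033)
  ser <- simulate_isotopes(tr, zero_noise_sim(
    sampling_days = c(0, 7, 9, 14, 21, 28, 35)), seed = 1)
  fit <- fit_turnover(ser, k = 0.051)
  dec <- decompose_turnover(fit, ser)
  at0 <- dec[dec$day == 0, ]
  expect_equal(unique(unlist(at0[c("observed", "predicted", "predicted_growth_only")])),
               8.53)
  pos <- dec[dec$day > 0, ]
  expect_true(all(pos$predicted_growth_only < pos$predicted))

  # with m = 0 the two predicted columns coincide
  fit0 <- fit
  fit0$m <- 0
  dec0 <- decompose_turnover(fit0, ser)
  expect_equal(dec0$predicted, dec0$predicted_growth_only)
})

test_that("bootstrap uncertainty is seeded, near zero without noise, and grows with noise", {
  tr <- treatment_config("x", base_k = 0.051, true_m = 0.033)
  days <- c(0, 7, 9, 14, 21, 28, 35)
  ser0 <- simulate_isotopes(tr, zero_noise_sim(sampling_days = days), seed = 1)
  fit0 <- fit_turnover(ser0, k = 0.051)
  bt0 <- bootstrap_turnover(fit0, n_boot = 100, seed = 1)
  expect_lt(bt0$m_se, 1e-8)

  serA <- simulate_isotopes(tr, sim_config(sampling_days = days,
                                           d15n_noise_sd = 0.1), seed = 2)
  serB <- simulate_isotopes(tr, sim_config(sampling_days = days,
                                           d15n_noise_sd = 0.4), seed = 2)
  btA <- bootstrap_turnover(fit_turnover(serA, k = 0.051), n_boot = 200, seed = 3)
  btB <- bootstrap_turnover(fit_turnover(serB, k = 0.051), n_boot = 200, seed = 3)
  expect_lt(btA$m_se, btB$m_se)

  btA2 <- bootstrap_turnover(fit_turnover(serA, k = 0.051), n_boot = 200, seed = 3)
  expect_identical(btA$m, btA2$m)

  ci <- confint(fit_turnover(serA, k = 0.051), n_boot = 150, seed = 5)
  expect_equal(rownames(ci), c("m", "t50"))
  expect_lt(ci["m", 1], ci["m", 2])
})
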