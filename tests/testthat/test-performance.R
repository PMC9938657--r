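test_that("weight gain matches the printed control arithmetic", {
  expect_equal(weight_gain_pct(3.38, 0.44), 100 * (3.38 - 0.44) / 0.44)
  expect_equal(round(weight_gain_pct(3.38, 0.44)), 668)
  expect_equal(weight_gain_pct(1.7, 1.7), 0)
  # group-mean arithmetic for T6 gives 634, not the per-tank-averaged 640
  expect_equal(weight_gain_pct(3.23, 0.44), 634.1, tolerance = 1e-3)
  expect_error(weight_gain_pct(3, 0), "> 0")
})

test_that("specific growth rate uses natural logs and is consistent with weight gain", {
  expect_equal(specific_growth_rate(3.38, 0.44, 35), 5.825, tolerance = 1e-3)
  expect_equal(specific_growth_rate(exp(1) * 0.5, 0.5, 1), 100)
  expect_error(specific_growth_rate(0, 1, 10), "> 0")
  expect_error(specific_growth_rate(1, 1, 0), "> 0")
  # algebraic identity sgr = 100 ln(1 + wg/100) / days, random inputs
  set.seed(42)
  for (i in 1:50) {
    iw <- runif(1, 0.1, 2); fw <- iw * exp(runif(1, -0.5, 3)); d <- runif(1, 1, 60)
    expect_equal(specific_growth_rate(fw, iw, d),
                 100 * log(1 + weight_gain_pct(fw, iw) / 100) / d,
                 tolerance = 1e-9)
  }
})

test_that("feed conversion ratio reproduces the printed table arithmetic", {
  expect_equal(feed_conversion_ratio(3.91, 3.38, 0.44), 1.330, tolerance = 1e-3)
  expect_equal(feed_conversion_ratio(2.94, 3.38, 0.44), 1.0)
  expect_equal(feed_conversion_ratio(3.44, 3.23, 0.44), 1.233, tolerance = 1e-3)
  expect_warning(out <- feed_conversion_ratio(1, 0.5, 0.5), "undefined")
  expect_true(is.nan(out))
})

test_that("feed saving reproduces the 5-12% range from the printed intakes", {
  expect_equal(feed_saving_pct(3.44, 3.91), 12.0, tolerance = 0.05)
  expect_equal(feed_saving_pct(3.70, 3.91), 5.4, tolerance = 0.05)
  expect_equal(feed_saving_pct(2.2, 2.2), 0)
  expect_error(feed_saving_pct(1, 0), "> 0")
  # scale invariance and antisymmetry around equal intake
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 1, 5); b <- runif(1, 1, 5); c <- runif(1, 0.5, 4)
    expect_equal(feed_saving_pct(a, b), feed_saving_pct(c * a, c * b),
                 tolerance = 1e-12)
    expect_equal(feed_saving_pct(b + (b - a), b), -feed_saving_pct(a, b) *
                   1, tolerance = 1e-9)
  }
})

test_that("survival removes sampled individuals from the denominator by contract", {
  expect_equal(survival_pct(9, 9), 100)
  expect_equal(survival_pct(28, 30), 93.3, tolerance = 0.05)
  expect_error(survival_pct(-1, 10), ">= 0")
  expect_error(survival_pct(5, 0), "> 0")
  expect_error(survival_pct(11, 10), "exceed")
})

test_that("interval SGR matches the closed form on simulated cohorts", {
  sim <- zero_noise_sim()
  trs <- default_treatments()
  wc <- simulate_weights(trs$Control, sim, seed = 1)
  # constant weights give zero growth
  w_const <- wc; w_const$weight <- 1.5
  expect_equal(interval_sgr(w_const, 0, 35)$sgr, rep(0, 3))
  # control closed form: 100 * base_k on any window
  expect_equal(interval_sgr(wc, 3, 21)$sgr, rep(5.83, 3), tolerance = 1e-6)
  # compensatory window: T6 interval SGR exceeds control on days 9-28
  w6 <- simulate_weights(trs$T6, sim, seed = 1)
  expect_true(all(interval_sgr(w6, 9, 28)$sgr > interval_sgr(wc, 9, 28)$sgr))
  expect_error(interval_sgr(wc, 0, 13), "day 13")
})

test_that("a default-calibrated simulated cohort reproduces the trial's performance pattern", {
  cohort <- simulate_cohort(default_treatments(), sim_config(seed = 2024))
  surv <- vapply(cohort$treatments, `[[`, 0, "survival_pct")
  rec <- performance_table(cohort$weights, cohort$feed, survival = surv)
  summ <- performance_summary(rec)
  ctrl <- summ[summ$treatment == "Control", ]
  expect_lt(abs(ctrl$wg_pct - 668) / 668, 0.05)
  # FCR ordering: Control > T3 ~ T6
  fcr <- setNames(summ$fcr, summ$treatment)
  expect_gt(fcr["Control"], fcr["T3"])
  expect_gt(fcr["Control"], fcr["T6"])
  expect_lt(abs(fcr["T3"] - fcr["T6"]), 0.15)
  expect_equal(unname(setNames(summ$survival_pct, summ$treatment)[c("Control", "T3", "T6")]),
               c(100, 97, 93))
})

test_that("pooled summary recomputes ratio metrics from treatment means", {
  cohort <- simulate_cohort(default_treatments(), sim_config(seed = 5))
  rec <- performance_table(cohort$weights, cohort$feed)
  pooled <- performance_summary(rec, pooled = TRUE)
  by_tank <- performance_summary(rec)
  ctrl_p <- pooled[pooled$treatment == "Control", ]
  expect_equal(ctrl_p$wg_pct,
               weight_gain_pct(ctrl_p$final_weight, ctrl_p$initial_weight))
  # the two averaging conventions differ, but only slightly
  expect_false(isTRUE(all.equal(pooled$wg_pct, by_tank$wg_pct)))
  expect_lt(max(abs(pooled$wg_pct - by_tank$wg_pct)), 30)
})
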