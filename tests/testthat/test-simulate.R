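test_that("noise-free weights follow the piecewise-exponential closed form", {
  sim <- zero_noise_sim()
  control <- treatment_config("Control", base_k = 0.0583)
  w <- simulate_weights(control, sim, seed = 1)
  w35 <- unique(round(w$weight[w$day == 35], 10))
  expect_length(w35, 1)
  expect_equal(w35, round(0.44 * exp(0.0583 * 35), 10))
  expect_equal(0.44 * exp(0.0583 * 35), 3.3856, tolerance = 1e-4)

  # brute-force day-stepping oracle for a restricted regime
  t6 <- treatment_config("T6", restriction_days = 6, compensatory_k = 0.0639)
  stepped <- 0.44
  for (d in 0:34) stepped <- stepped * exp(phase_rate(t6, d))
  w6 <- simulate_weights(t6, sim, seed = 1)
  expect_equal(unique(round(w6$weight[w6$day == 35], 10)),
               round(stepped, 10))
})

test_that("no restriction degenerates to the control trajectory", {
  sim <- zero_noise_sim()
  a <- simulate_weights(treatment_config("A"), sim, seed = 7)
  b <- simulate_weights(treatment_config("B", restriction_days = 0,
                                         compensatory_k = 0.09,
                                         recovery_end_day = 0),
                        sim, seed = 7)
  expect_equal(a$weight, b$weight)
})

test_that("restricted regimes dip below the control and converge by day 35", {
  sim <- zero_noise_sim()
  trs <- default_treatments()
  wc <- simulate_weights(trs$Control, sim, seed = 1)
  w6 <- simulate_weights(trs$T6, sim, seed = 1)
  at <- function(w, d) mean(w$weight[w$day == d])
  expect_lt(at(w6, 6), at(wc, 6))
  expect_lt(at(w6, 9), at(wc, 9))
  # converged: within 5% of control at day 35
  expect_lt(abs(at(w6, 35) - at(wc, 35)) / at(wc, 35), 0.05)
})

test_that("weights are strictly increasing in time when rates are positive and noise is off", {
  sim <- zero_noise_sim()
  for (tr in default_treatments()) {
    w <- simulate_weights(tr, sim, seed = 3)
    traj <- aggregate(weight ~ day, w, mean)
    expect_true(all(diff(traj$weight[order(traj$day)]) > 0))
  }
})

test_that("isotope series start at the baseline and approach the asymptote monotonically", {
  sim <- zero_noise_sim()
  tr <- treatment_config("C", base_k = 0.051, true_m = 0.033)
  ser <- simulate_isotopes(tr, sim, seed = 1)
  expect_equal(unique(ser$d15n[ser$day == 0]), 8.53)
  mu <- tapply(ser$d15n, ser$day, mean)
  expect_true(all(diff(mu[order(as.numeric(names(mu)))]) > 0))
  expect_true(all(ser$d15n[ser$day > 0] > 8.53 & ser$d15n[ser$day > 0] < 14.31))
})

test_that("noise-free isotope value matches scalar arithmetic at k + m = 0.084, t = 35", {
  # constant-k regime so the exposure is exactly (k + m) t
  tr <- treatment_config("C", base_k = 0.051, true_m = 0.033)
  sim <- zero_noise_sim()
  ser <- simulate_isotopes(tr, sim, seed = 1)
  expect_equal(unique(ser$d15n[ser$day == 35]),
               14.31 + (8.53 - 14.31) * exp(-0.084 * 35))
  expect_equal(14.31 + (8.53 - 14.31) * exp(-0.084 * 35), 14.00, tolerance = 5e-4)
})

test_that("isotope noise has the configured standard deviation", {
  tr <- treatment_config("C", true_m = 0.02)
  sim <- sim_config(sampling_days = c(0, 14), isotope_reps = 500,
                    d15n_noise_sd = 0.2)
  ser <- simulate_isotopes(tr, sim, seed = 11)
  s <- sd(ser$d15n[ser$day == 14])
  expect_gt(s, 0.18)
  expect_lt(s, 0.22)
})

test_that("invalid generator configs are rejected", {
  expect_error(sim_config(d15n_noise_sd = -0.1), ">=")
  expect_error(sim_config(initial_weight_mean = 0), "> 0")
  expect_error(sim_config(sampling_days = c(3, 6)), "start at day 0")
  expect_error(sim_config(sampling_days = c(0, 6, 6)), "strictly increasing")
  expect_error(sim_config(d15n_baseline = 10, d15n_asymptote = 10), "differ")
  expect_error(treatment_config("x", restriction_fraction = 1.2), "\\[0, 1\\]")
  expect_error(treatment_config("x", restricted_k = 0.08), "exceed")
})

test_that("feed follows the ration-fraction schedule", {
  sim <- zero_noise_sim()
  t6 <- default_treatments()$T6
  feed <- simulate_feed(t6, sim)
  biomass0 <- sim$shrimp_per_tank * sim$initial_weight_mean
  # restriction day 0: fraction is 0.11 * (1 - 0.7) = 0.033
  expect_equal(feed$offered_g[feed$day == 0][1], 0.033 * biomass0)

  control <- default_treatments()$Control
  fc <- simulate_feed(control, sim)
  fc1 <- fc[fc$tank == fc$tank[1], ]
  expected <- 0.11 * biomass0 * exp(log_growth(control, fc1$day))
  expect_equal(fc1$offered_g, expected)

  # cumulative feed per shrimp: restricted T6 saves feed vs control
  per_shrimp <- function(f) sum(f$offered_g[f$tank == f$tank[1]]) / sim$shrimp_per_tank
  expect_lt(per_shrimp(feed), per_shrimp(fc))
})

test_that("Dirichlet-multinomial OTU tables are reproducible with fixed column sums", {
  p <- default_taxa_profile()
  expect_equal(sum(p), 1)
  a <- simulate_otu_table(5, p, depth = 2000, seed = 5)
  b <- simulate_otu_table(5, p, depth = 2000, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_true(all(colSums(a$counts) == 2000))
  expect_error(simulate_otu_table(2, c(a = 0.5, b = 0.4), depth = 10),
               "sum to 1")
})

test_that("OTU profile concentration controls Shannon diversity", {
  one <- c(a = 1); attr(one, "taxonomy") <- "P;C;O;F;G"
  tab <- simulate_otu_table(3, one, depth = 500, seed = 1)
  expect_equal(unname(apply(tab$counts, 2, shannon_index)), c(0, 0, 0))

  unif <- setNames(rep(0.1, 10), paste0("o", 1:10))
  attr(unif, "taxonomy") <- paste0("P;C;O;F;G", 1:10)
  big <- simulate_otu_table(3, unif, depth = 2e5, seed = 2,
                            overdispersion = 1e6)
  h <- apply(big$counts, 2, shannon_index)
  expect_equal(unname(h), rep(log(10), 3), tolerance = 0.01)
})

test_that("identical configs and seed give bit-identical cohorts", {
  sim <- sim_config(seed = 9)
  a <- simulate_cohort(default_treatments(), sim)
  b <- simulate_cohort(default_treatments(), sim)
  expect_identical(a$weights, b$weights)
  expect_identical(a$feed, b$feed)
  expect_identical(a$isotopes, b$isotopes)
})

test_that("the fitter recovers the generating m from a noise-free series", {
  sim <- zero_noise_sim(sampling_days = c(0, 7, 9, 14, 21, 28, 35))
  for (m_true in c(0.008, 0.018, 0.033)) {
    tr <- treatment_config("x", base_k = 0.057, true_m = m_true)
    ser <- simulate_isotopes(tr, sim, seed = 1)
    fit <- fit_turnover(ser, k = 0.057)
    expect_lt(abs(fit$m - m_true), 1e-6)
  }
})
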