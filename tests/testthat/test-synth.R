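test_that("simulated spectra follow the three-band mixture construction", {
  sp <- spectral_model_params(noise_sd = 0, bleach_rate = 0)
  folded <- simulate_spectrum(sp, 0, 0)
  expect_gt(intensity_at(folded, 330), intensity_at(folded, 365))
  unfolded <- simulate_spectrum(spectral_model_params(noise_sd = 0, kappa = 1),
                                1, 0)
  expect_gt(compute_rfi(unfolded), compute_rfi(folded))
  # at kappa = 1, f = 1 the 330 nm signal is only exposed-band tails
  w <- sp$band_centers
  tails <- 0.6 * exp(-(330 - 344)^2 / (2 * 20^2)) +
    0.4 * exp(-(330 - 365)^2 / (2 * 20^2))
  expect_equal(intensity_at(unfolded, 330), 1000 * tails, tolerance = 1e-6)
  expect_error(simulate_spectrum(sp, 1.2, 0), "\\[0, 1\\]")
})

test_that("simulation is deterministic under a seed and varies across seeds", {
  sp <- spectral_model_params(noise_sd = 20)
  a <- simulate_spectrum(sp, 0.5, 8, rng_seed = 42)
  b <- simulate_spectrum(sp, 0.5, 8, rng_seed = 42)
  c <- simulate_spectrum(sp, 0.5, 8, rng_seed = 43)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
  kp <- kinetics_true_params()
  s1 <- simulate_denaturation_series(kp, sp, rng_seed = 1)
  s2 <- simulate_denaturation_series(kp, sp, rng_seed = 1)
  expect_identical(s1$spectra[[5]]$intensities, s2$spectra[[5]]$intensities)
})

test_that("rfi is scale invariant and strictly increasing for noiseless kinetics", {
  kp <- kinetics_true_params()
  for (kappa in c(0.2, 0.5, 1)) {
    sp <- spectral_model_params(noise_sd = 0, bleach_rate = 0, kappa = kappa)
    rfi <- rfi_series(simulate_denaturation_series(kp, sp))$rfi_values
    expect_true(all(diff(rfi) > 0))
    sp10 <- spectral_model_params(noise_sd = 0, bleach_rate = 0, kappa = kappa,
                                  base_amplitude = 10000)
    rfi10 <- rfi_series(simulate_denaturation_series(kp, sp10))$rfi_values
    expect_equal(rfi10, rfi, tolerance = 1e-9)
  }
  # uniform bleach cancels out of the ratio too
  spb <- spectral_model_params(noise_sd = 0, bleach_rate = 0.05)
  sp0 <- spectral_model_params(noise_sd = 0, bleach_rate = 0)
  expect_equal(rfi_series(simulate_denaturation_series(kp, spb))$rfi_values,
               rfi_series(simulate_denaturation_series(kp, sp0))$rfi_values,
               tolerance = 1e-9)
})

test_that("the logistic midpoint lands near 50% denaturation at t50 after anchoring", {
  nrm <- noiseless_normalized(kinetics_true_params(t50 = 8, slope_b = 1.5))
  at8 <- percent_at_time(nrm, 8)
  expect_gt(at8, 30); expect_lt(at8, 60)
})

test_that("cohort generator hits the calibration medians and group structure", {
  co <- simulate_cohort(cohort_sim_params(seed = 5))
  expect_equal(nrow(co), 44L)
  expect_equal(sum(co$group == "ACS"), 24L)
  expect_equal(sum(co$group == "control"), 20L)
  expect_true(all(co$statin_use[co$group == "control"] == 0))
  # determinism
  expect_identical(co, simulate_cohort(cohort_sim_params(seed = 5)))
  expect_false(identical(co$pct_denat_8h,
                         simulate_cohort(cohort_sim_params(seed = 6))$pct_denat_8h))
  # large-n medians converge to the printed calibration targets (LLN)
  big <- simulate_cohort(cohort_sim_params(n_cases = 10000, n_controls = 10000,
                                           seed = 11))
  med <- tapply(big$pct_denat_8h, big$group, median)
  expect_equal(unname(med["ACS"]), 64.9, tolerance = 0.02 * 64.9)
  expect_equal(unname(med["control"]), 23.3, tolerance = 0.02 * 23.3)
  iqr <- tapply(big$pct_denat_8h, big$group, function(x)
    unname(quantile(x, c(0.25, 0.75))))
  expect_equal(iqr$ACS, c(58.7, 78.4), tolerance = 0.03 * 70)
  expect_equal(iqr$control, c(20.3, 27.0), tolerance = 0.03 * 24)
  # statin prevalence near 88% in cases
  expect_equal(mean(big$statin_use[big$group == "ACS"]), 21 / 24,
               tolerance = 0.02)
})

test_that("group stability scores separate at the interquartile level", {
  # IQRs of the two groups must not overlap at the default calibration
  for (seed in 1:20) {
    co <- simulate_cohort(cohort_sim_params(seed = 100 + seed))
    q <- tapply(co$pct_denat_8h, co$group, quantile, c(0.25, 0.75))
    expect_lt(q$control[2], q$ACS[1])
  }
})

test_that("cohort covariates correlate with the score with the calibrated signs", {
  big <- simulate_cohort(cohort_sim_params(n_cases = 2000, n_controls = 2000,
                                           seed = 21))
  sc <- spearman_screen(big)
  rho <- setNames(sc$rho, sc$variable)
  expect_lt(rho["apo_a1"], 0)
  expect_gt(rho["hdl_triglycerides"], 0)
  expect_lt(rho["hdl_cholesterol"], 0)
  expect_gt(rho["glucose"], 0)
  expect_lt(rho["total_cholesterol"], 0)
})
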