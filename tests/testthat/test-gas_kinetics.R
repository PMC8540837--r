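test_that("Henry partitioning reproduces the dissolved-CH4 working concentrations", {
  # 0.1% and 1% headspace at the two incubation temperatures
  expect_equal(dissolved_ch4(1000, 8), 2.0, tolerance = 0.10)
  expect_equal(dissolved_ch4(1000, 15), 1.7, tolerance = 0.10)
  expect_equal(dissolved_ch4(10000, 8), 20, tolerance = 0.10)
  expect_equal(dissolved_ch4(10000, 15), 17, tolerance = 0.10)
})

test_that("dissolved_ch4 is linear in mixing ratio and decreasing in temperature", {
  expect_identical(dissolved_ch4(0, 12), 0)
  expect_equal(dissolved_ch4(2000, 8), 2 * dissolved_ch4(1000, 8))
  temps <- seq(0, 30, by = 2)
  d <- dissolved_ch4(rep(1000, length(temps)), temps)
  expect_true(all(diff(d) < 0))
  expect_error(dissolved_ch4(-1, 8), "non-negative")
  expect_error(dissolved_ch4(1000, -300), "absolute zero")
})

test_that("injection arithmetic reproduces the culture headspace series", {
  b <- bottle_spec(125, 21.6, temp_C = 8)
  expect_equal(headspace_after_injection(b, 0.2, 0.95), 1900, tolerance = 0.10)
  expect_equal(headspace_after_injection(b, 0.6, 0.95), 5400, tolerance = 0.10)
  expect_equal(headspace_after_injection(b, 1.5, 0.95), 13000, tolerance = 0.10)
  expect_equal(headspace_after_injection(b, 3.0, 0.95), 25000, tolerance = 0.10)
  expect_identical(headspace_after_injection(b, 0, 0.95), 0)
  expect_error(headspace_after_injection(b, -1), "non-negative")
})

test_that("headspace_moles follows the ideal gas law", {
  b <- bottle_spec(50, 4, temp_C = 8)  # 46 mL headspace at 281.15 K
  # hand evaluation: 1 * 0.046 * 0.01 / (0.082057 * 281.15) mol
  expect_equal(headspace_moles(b, 10000),
               1 * 0.046 * 0.01 / (0.082057 * 281.15) * 1e6,
               tolerance = 1e-12)
  expect_identical(headspace_moles(b, 0), 0)
  expect_equal(headspace_moles(b, 20000), 2 * headspace_moles(b, 10000))
})

test_that("injection followed by mole conversion round-trips PV = nRT", {
  # moles implied by the post-injection mixing ratio in the expanded gas
  # phase must equal the directly computed injected moles
  for (v in c(0.2, 0.6, 1.5, 3)) {
    b <- bottle_spec(125, 21.6, temp_C = 8)
    ppm <- headspace_after_injection(b, v, ch4_purity = 1)
    expanded <- bottle_spec(125 + v, 21.6, temp_C = 8)
    direct <- 1 * (v / 1000) / (0.082057 * 281.15) * 1e6
    expect_equal(headspace_moles(expanded, ppm), direct, tolerance = 1e-10)
  }
})

test_that("total CH4 mass combines headspace and dissolved phases", {
  dry <- bottle_spec(50, 0, temp_C = 8)
  expect_equal(total_ch4_mass(dry, 5000), headspace_moles(dry, 5000))
  b <- bottle_spec(125, 21.6, temp_C = 8)
  expect_equal(total_ch4_mass(b, 1900),
               headspace_moles(b, 1900) +
                 dissolved_ch4(1900, 8) * 21.6 / 1000)
  # more liquid under a fixed headspace holds more CH4
  liq <- seq(0, 100, by = 20)
  masses <- sapply(liq, function(L)
    total_ch4_mass(bottle_spec(103.4 + L, L, temp_C = 8), 1900))
  expect_true(all(diff(masses) > 0))
})

test_that("sampling corrections: identity with no sampling, zero oxidation for constant series", {
  b <- bottle_spec(125, 21.6, temp_C = 8)
  t <- c(0, 2, 4, 8)
  decay <- gas_timeseries(t, 1900 * exp(-0.1 * t), b)
  out <- apply_sampling_corrections(decay)
  expect_equal(out$removed_cum_umol, rep(0, 4))
  expect_equal(out$oxidized_cum_umol,
               total_ch4_mass(b, 1900) - sapply(decay$ch4_ppm, total_ch4_mass,
                                                bottle = b))
  const <- gas_timeseries(t, rep(1900, 4), b,
                          gas_sample_mL = 0.5, liquid_sample_mL = 0.34)
  outc <- apply_sampling_corrections(const)
  expect_true(all(abs(outc$oxidized_cum_umol) <
                    1e-9 * attr(outc, "initial_umol")))
  expect_true(all(diff(outc$removed_cum_umol) > 0))
})

test_that("sampling corrections conserve mass and match the closed form", {
  b <- bottle_spec(50, 0, temp_C = 8)
  t <- 0:5
  s <- gas_timeseries(t, 2000 * exp(-0.05 * t), b, gas_sample_mL = 0.5)
  out <- apply_sampling_corrections(s)
  init <- attr(out, "initial_umol")
  expect_true(all(abs(out$oxidized_cum_umol + out$removed_cum_umol +
                        out$residual_umol - init) < 1e-9 * init))
  # gas-only constant series: removed mass telescopes to 1 - (1-f)^m
  f <- 0.5 / b$headspace_mL
  cs <- gas_timeseries(t, rep(2000, 6), b, gas_sample_mL = 0.5)
  outc <- apply_sampling_corrections(cs)
  m0 <- attr(outc, "initial_umol")
  expect_equal(outc$removed_cum_umol[6], m0 * (1 - (1 - f)^5),
               tolerance = 1e-12)
  expect_error(apply_sampling_corrections(
    gas_timeseries(t, rep(1, 6), b, gas_sample_mL = 60)), "smaller")
})

test_that("first-order fit recovers noiseless exponentials to numerical precision", {
  b <- bottle_spec(50, 0, temp_C = 8)
  t <- c(0, 10, 20, 30)
  for (k in 10^seq(-3, 0, by = 0.5)) {
    fit <- fit_first_order(gas_timeseries(t, 1000 * exp(-k * t), b))
    expect_lt(abs(fit$k - k) / k, 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_equal(exp(fit$intercept), 1000, tolerance = 1e-9)
  }
})

test_that("degenerate and invalid series are handled explicitly", {
  b <- bottle_spec(50, 0, temp_C = 8)
  const <- gas_timeseries(c(0, 10, 20), rep(500, 3), b)
  fit <- fit_first_order(const)
  expect_identical(fit$k, 0)
  expect_identical(fit$r_squared, 0)
  expect_true(fit$degenerate)
  expect_error(gas_timeseries(c(0, 5), c(100, -1), b), "non-negative")
  expect_error(fit_first_order(gas_timeseries(c(0, 5, 9), c(100, 0, 2), b)),
               "positive")
  expect_error(gas_timeseries(0, 100, b), "at least 2")
  expect_warning(
    fit_first_order(gas_timeseries(c(0, 5, 10), c(100, 120, 160), b)),
    "production")
})

test_that("noisy rate recovery: accurate median, near-unbiased mean, calibrated CIs", {
  b <- bottle_spec(50, 0, temp_C = 8)
  k_true <- 0.05
  set.seed(42)
  res <- t(replicate(200, {
    s <- gen_gas_series(k_true, 5000, times_h = c(0, 10, 20, 30),
                        noise_sd = 0.05, bottle = b)
    f <- fit_first_order(s)
    c(f$k, f$k_ci95)
  }))
  rel_err <- abs(res[, 1] - k_true) / k_true
  expect_lt(median(rel_err), 0.05)
  expect_lt(abs(mean(res[, 1]) - k_true) / k_true, 0.02)
  covered <- res[, 2] <= k_true & k_true <= res[, 3]
  expect_gte(mean(covered), 0.90)
})

test_that("equal-dissolved concentration comparison across temperatures", {
  # a 1000 ppm headspace at 8 degC dissolves like a ~16% higher one at 15 degC
  expect_equal(equivalent_ppm(1000, 8, 15) / 1000,
               henry_kH(8) / henry_kH(15), tolerance = 1e-12)
  expect_equal(equivalent_ppm(1000, 8, 15), 1163, tolerance = 0.01)
  expect_equal(dissolved_ch4(equivalent_ppm(1000, 8, 15), 15),
               dissolved_ch4(1000, 8), tolerance = 1e-12)
  expect_equal(rate_at_concentration(0.1, 20), 2)
  expect_identical(rate_at_concentration(0.1, 0), 0)
})

test_that("dry-weight normalisation does the unit algebra", {
  soil <- soil_context(4, 0.8)
  expect_equal(soil$dry_g, 0.8)
  expect_equal(rate_per_dry_weight(1, soil), 16.04 * 24 / 0.8)
  half <- soil_context(2, 0.8)
  expect_equal(rate_per_dry_weight(1, half), 2 * rate_per_dry_weight(1, soil))
  expect_error(soil_context(4, 1), "water_fraction")
})

test_that("OD-to-cell standard: exact on collinear points, sane on noisy ones", {
  od <- seq(0.01, 0.7, length.out = 10)
  counts <- 1e8 * od + 1e5
  std <- fit_cell_standard(od, counts)
  expect_equal(std$r_squared, 1)
  expect_equal(cells_from_od(od, std), counts, tolerance = 1e-9)
  # 14-point standard emulating the culture's OD and count ranges
  set.seed(7)
  od14 <- seq(0.0085, 0.7295, length.out = 14)
  true_line <- 6.1e5 + (7.266e7 - 6.1e5) * (od14 - od14[1]) / diff(range(od14))
  noisy <- true_line * (1 + rnorm(14, 0, 0.15))
  std14 <- fit_cell_standard(od14, noisy)
  expect_gt(std14$r_squared, 0.8)
  pred <- suppressWarnings(cells_from_od(od14, std14))  # low-OD clamping ok
  resid_sd <- sd(noisy - pred)
  expect_true(all(abs(pred - true_line) < 4 * resid_sd))
  expect_warning(low <- cells_from_od(-5, std14), "clamping")
  expect_identical(low, 0)
})

test_that("per-cell rate normalisation", {
  expect_equal(rate_per_cell(0.5, 5e7, 21.6), 0.5 / (5e7 * 21.6) * 1e8)
  expect_equal(rate_per_cell(0.5, 1e8, 21.6),
               rate_per_cell(0.5, 5e7, 21.6) / 2)
  expect_identical(rate_per_cell(0, 5e7, 21.6), 0)
  expect_error(rate_per_cell(0.5, 0, 21.6), "positive")
})
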