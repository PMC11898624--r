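test_that("Magnus conversion matches hand-evaluated values", {
  expect_equal(e_sat_hPa(20), 23.32596, tolerance = 1e-6)
  expect_equal(rh_to_h2o(0, 20, 101.325), 0)
  expect_equal(rh_to_h2o(50, 20, 101.325), 11510.47, tolerance = 1e-6)
  expect_error(rh_to_h2o(-1, 20, 101.325), "negative")
  expect_error(rh_to_h2o(50, 20, 0), "pressure")
  expect_error(rh_to_h2o(50, 40, 5), "saturation")
})

test_that("ratio-mode dilution correction reproduces the closed-form rescaling", {
  expect_equal(dilution_correct_o2(209000, 0, 0, method = "ratio"), 209000)
  expect_equal(dilution_correct_o2(209000, 20000, 1000, method = "ratio"),
               209000 / 0.979, tolerance = 1e-9)
  expect_error(dilution_correct_o2(209000, 999999, 1000, method = "ratio"),
               "below 1e6")
})

test_that("inert-mode correction removes dilution but keeps O2 exchange", {
  # evaporating chamber, true RQ 1: corrected slope must equal -CO2 slope,
  # uncorrected and ratio-corrected slopes are steeper (dilution bias)
  cfg <- noise_free_config(rq_true = 1, evap_rate = 2)
  cyc <- simulate_cycle(cfg, std_chamber(), std_env())
  win <- extract_fit_window(cyc)
  h2o <- rh_to_h2o(win$rh_pct, win$temp_C, win$pressure_kPa)
  o2_inert <- dilution_correct_o2(win$o2_ppm_wet, h2o, win$co2_ppm)
  inert <- 1e6 - win$o2_ppm_wet - h2o - win$co2_ppm
  co2_inert <- win$co2_ppm * inert[1] / inert # CO2 on the same inert reference
  s_co2 <- fit_slope(win$t_s, co2_inert)$slope_ppm_s
  s_corr <- fit_slope(win$t_s, o2_inert)$slope_ppm_s
  s_raw <- fit_slope(win$t_s, win$o2_ppm_wet)$slope_ppm_s
  expect_lt(abs(s_corr + s_co2) / s_co2, 0.001)
  expect_lt(s_raw, s_corr) # uncorrected decline strictly steeper
})

test_that("dilution correction commutes with windowing", {
  cfg <- noise_free_config(rq_true = 0.8, evap_rate = 2)
  cyc <- simulate_cycle(cfg, std_chamber(), std_env())
  h2o_full <- rh_to_h2o(cyc$rh_pct, cyc$temp_C, cyc$pressure_kPa)
  corr_full <- dilution_correct_o2(cyc$o2_ppm_wet, h2o_full, cyc$co2_ppm)
  win <- extract_fit_window(cyc)
  h2o_win <- rh_to_h2o(win$rh_pct, win$temp_C, win$pressure_kPa)
  corr_win <- dilution_correct_o2(win$o2_ppm_wet, h2o_win, win$co2_ppm)
  s_full <- fit_slope(win$t_s, corr_full[cyc$t_s >= 300 & cyc$t_s < 1500])$slope_ppm_s
  s_win <- fit_slope(win$t_s, corr_win)$slope_ppm_s
  expect_equal(s_win, s_full, tolerance = 1e-3)
})

test_that("fit window is [300 s, 1500 s) on the 10-s grid", {
  cyc <- simulate_cycle(noise_free_config(), std_chamber(), std_env())
  win <- extract_fit_window(cyc)
  expect_equal(nrow(win), 120)
  expect_false(290 %in% win$t_s)
  expect_true(300 %in% win$t_s)
  expect_true(1490 %in% win$t_s)
  expect_false(1500 %in% win$t_s)
  short <- cyc[cyc$t_s <= 1200, ]
  expect_error(extract_fit_window(short), "25 min")
})

test_that("slope fitting handles exact, degenerate and noisy inputs", {
  t <- seq(0, 990, 10)
  fit <- fit_slope(t, 400 + 0.05 * t)
  expect_equal(fit$slope_ppm_s, 0.05, tolerance = 1e-12)
  expect_equal(fit$intercept_ppm, 400, tolerance = 1e-9)
  expect_equal(fit$r2, 1)

  flat <- fit_slope(t, rep(400, length(t)))
  expect_equal(flat$slope_ppm_s, 0)
  expect_equal(flat$r2, 0)

  expect_error(fit_slope(rep(1, 5), 1:5), "constant")
  expect_error(fit_slope(1:2, 1:2), "3 points")

  # noisy simulated cycle: slope within 2 closed-form OLS SEs of the truth
  ch <- std_chamber(); env <- std_env()
  cfg <- simulation_config(resp_flux = 2, rq_true = 1, evap_rate = 0,
                           noise_sd_co2 = 2, noise_sd_o2 = 0, seed = 1L)
  cyc <- simulate_cycle(cfg, ch, env)
  win <- extract_fit_window(cyc)
  truth_slope <- cfg$resp_flux * ch$area_m2 / headspace_umol(ch, env) * 1e6
  se <- 2 / sqrt(sum((win$t_s - mean(win$t_s))^2))
  fit <- fit_slope(win$t_s, win$co2_ppm)
  expect_lt(abs(fit$slope_ppm_s - truth_slope), 2 * se)

  # closed-form fit agrees with stats::lm on the same data
  ref <- stats::lm(co2_ppm ~ t_s, data = win)
  expect_equal(fit$slope_ppm_s, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(fit$intercept_ppm, unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(fit$r2, summary(ref)$r.squared, tolerance = 1e-12)
})

test_that("QC flags implement the r2, humidity and sign screens", {
  t <- seq(0, 990, 10)
  up <- fit_slope(t, 400 + 0.05 * t)
  down <- fit_slope(t, 209000 - 0.05 * t)

  good <- qc_flags(up, down, rh_window_pct = 80)
  expect_true(good$overall)

  lowr2 <- up; lowr2$r2 <- 0.95
  expect_false(qc_flags(lowr2, down, 80)$overall)
  expect_false(qc_flags(lowr2, down, 80)$pass_r2_co2)

  expect_false(qc_flags(up, down, 99.5)$overall)
  expect_true(qc_flags(up, down, 99.0)$pass_rh)

  expect_false(qc_flags(down, down, 80)$pass_sign)

  # threshold is configuration: r2_min = 0 retains a sloppy fit
  expect_true(qc_flags(lowr2, down, 80, r2_min = 0)$overall)
})

test_that("gap filling interpolates only gaps strictly shorter than 2 h", {
  one <- fill_gaps(c(2, NA, 3))
  expect_equal(one$value, c(2, 2.5, 3))
  expect_equal(one$interpolated, c(FALSE, TRUE, FALSE))

  three <- fill_gaps(c(1, NA, NA, NA, 5))
  expect_equal(three$value, c(1, NA, NA, NA, 5))

  two <- fill_gaps(c(1, NA, NA, 5)) # 2-h gap is not strictly < 2 h
  expect_true(all(is.na(two$value[2:3])))

  none <- fill_gaps(c(1, 2, 3))
  expect_equal(none$value, c(1, 2, 3))
  expect_false(any(none$interpolated))

  lead <- fill_gaps(c(NA, 2, 3))
  expect_true(is.na(lead$value[1]))

  # finer grid: a 1.5-h gap (3 points at 30 min) is filled
  fine <- fill_gaps(c(1, NA, NA, NA, 5), dt_h = 0.5)
  expect_equal(fine$value, c(1, 2, 3, 4, 5))
})
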