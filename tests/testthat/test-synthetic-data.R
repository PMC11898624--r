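test_that("noise-free cycles invert exactly: a prescribed CO2 slope is recovered", {
  ch <- std_chamber(); env <- std_env()
  n_tot <- headspace_umol(ch, env)
  # choose the efflux so the noise-free CO2 slope is exactly 0.05 ppm/s
  flux <- 0.05 * n_tot / (ch$area_m2 * 1e6)
  cfg <- noise_free_config(resp_flux = flux, rq_true = 1, evap_rate = 0)
  cyc <- simulate_cycle(cfg, ch, env)
  fit <- fit_slope(cyc$t_s, cyc$co2_ppm)
  expect_equal(fit$slope_ppm_s, 0.05, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("equimolar exchange gives mirror-image corrected O2 and CO2 slopes", {
  cfg <- noise_free_config(rq_true = 1, evap_rate = 0)
  cyc <- simulate_cycle(cfg, std_chamber(), std_env())
  h2o <- rh_to_h2o(cyc$rh_pct, cyc$temp_C, cyc$pressure_kPa)
  o2c <- dilution_correct_o2(cyc$o2_ppm_wet, h2o, cyc$co2_ppm)
  s_co2 <- fit_slope(cyc$t_s, cyc$co2_ppm)$slope_ppm_s
  s_o2 <- fit_slope(cyc$t_s, o2c)$slope_ppm_s
  expect_lt(abs(s_o2 + s_co2) / s_co2, 0.001)
})

test_that("cycle simulation is bit-identical under a fixed seed", {
  cfg <- simulation_config(noise_sd_co2 = 2, noise_sd_o2 = 2, seed = 11L)
  a <- simulate_cycle(cfg, std_chamber(), std_env())
  b <- simulate_cycle(cfg, std_chamber(), std_env())
  expect_identical(a$co2_ppm, b$co2_ppm)
  expect_identical(a$o2_ppm_wet, b$o2_ppm_wet)
  cfg2 <- simulation_config(noise_sd_co2 = 2, noise_sd_o2 = 2, seed = 12L)
  c <- simulate_cycle(cfg2, std_chamber(), std_env())
  expect_false(identical(a$co2_ppm, c$co2_ppm))
})

test_that("headspace molar bookkeeping conserves mass to 1e-9 relative", {
  cfg <- noise_free_config(resp_flux = 2, rq_true = 0.7, evap_rate = 1)
  cyc <- simulate_cycle(cfg, std_chamber(), std_env())
  truth <- attr(cyc, "truth")
  ch <- std_chamber()
  expected_gain <- (cfg$resp_flux - cfg$resp_flux / cfg$rq_true + cfg$evap_rate) *
    ch$area_m2 * truth$t_s
  gain <- truth$n_tot - truth$n_tot[1]
  expect_equal(gain, expected_gain, tolerance = 1e-9)
  # component bookkeeping adds up
  expect_equal(truth$n_co2 + truth$n_o2 + truth$n_h2o + truth$n_inert,
               truth$n_tot, tolerance = 1e-12)
})

test_that("measurement-model inversion holds across the flux range, noise free", {
  ch <- std_chamber(); env <- std_env()
  for (flux in c(0.1, 1, 10)) {
    cfg <- noise_free_config(resp_flux = flux, rq_true = 0.85, evap_rate = 2)
    rec <- process_cycle(simulate_cycle(cfg, ch, env), chamber = ch)
    expect_lt(abs(rec$e_co2 - flux) / flux, 1e-3)
    expect_equal(rec$arq, 0.85, tolerance = 1e-3)
  }
})

test_that("a one-day campaign yields 24 hourly cycles per chamber", {
  camp <- simulate_campaign(simulation_config(seed = 3L),
                            list(std_chamber("A"), std_chamber("B")), n_days = 1)
  per_chamber <- table(sub("_c.*", "", unique(camp$cycle_id)))
  expect_equal(unname(per_chamber[["A"]]), 24)
  expect_equal(unname(per_chamber[["B"]]), 24)
  # chambers carry independent noise realizations
  a <- camp[camp$tree_id == "A", ]
  b <- camp[camp$tree_id == "B", ]
  expect_false(identical(a$co2_ppm, b$co2_ppm))
})

test_that("linear sensor drift accumulates at the configured daily rate", {
  cfg <- noise_free_config(resp_flux = 2, rq_true = 1, evap_rate = 0,
                           drift_ppm_per_day = 10, diel_temp = c(15, 5), seed = 5L)
  camp <- simulate_campaign(cfg, list(std_chamber("A")), n_days = 22)
  first <- camp[camp$cycle_id == "A_c0001", ]
  # cycle closing exactly 21 days after the first, same diel phase
  late_id <- sprintf("A_c%04d", 21 * 24 + 1)
  late <- camp[camp$cycle_id == late_id, ]
  expect_equal(late$co2_ppm - first$co2_ppm, rep(210, nrow(first)),
               tolerance = 1e-9)
})

test_that("flask simulator mixes endmembers linearly and dates fixation years", {
  atm <- make_linear_atmosphere(2018, 2.3, 4.7, 2)
  s0 <- simulate_flask(substrate_mix(f_lipid = 0), atm, 2018, 1200)
  expect_equal(s0$d13c_permil, -27.11)
  expect_equal(s0$D14C_permil, 2.3)
  s5 <- simulate_flask(substrate_mix(f_lipid = 0.5), atm, 2018, 1200)
  expect_equal(s5$d13c_permil, -29.125)
  expect_error(
    simulate_flask(substrate_mix(f_lipid = 0, age_years = 10), atm, 2018, 1200),
    "outside")
})

test_that("linear atmosphere records decline at the configured rate", {
  atm <- make_linear_atmosphere(2018, 2.3, 4.7, 2)
  expect_equal(atm_lookup(atm, 2019), -2.4)
  flat <- make_linear_atmosphere(2000, 50, 0, 10)
  expect_equal(atm_lookup(flat, c(2000, 2005, 2009)), rep(50, 3))
  long <- make_linear_atmosphere(2000, 100, 4.7, 22)
  expect_equal(atm_lookup(long, 2021), 100 - 4.7 * 21)
})

test_that("ORO image generator hits the target coverage and is reproducible", {
  blank <- simulate_oro_image(0, c(20, 60), 10, c(400, 200), seed = 1)
  expect_equal(blank$true_coverage_pct, 0)
  expect_true(all(blank$pixels[, , 1] > 0.9))

  img <- simulate_oro_image(1, c(20, 60), 10, c(1200, 400), seed = 2)
  expect_lt(abs(img$true_coverage_pct - 1), 0.02)
  # realized coverage is the exact pixel count of the red mask
  expect_equal(mean(stain_mask(img)) * 100, img$true_coverage_pct,
               tolerance = 1e-12)

  again <- simulate_oro_image(1, c(20, 60), 10, c(1200, 400), seed = 2)
  expect_identical(img$pixels, again$pixels)

  expect_error(
    simulate_oro_image(50, c(80, 100), 1, c(300, 300), seed = 1,
                       max_attempts = 200),
    "packing")
})

test_that("sensor logs and flask tables round-trip through CSV", {
  camp <- simulate_campaign(simulation_config(seed = 9L),
                            list(std_chamber("A")), n_days = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_log(camp, path)
  back <- read_sensor_log(path)
  expect_equal(nrow(back), nrow(camp))
  expect_equal(back$co2_ppm, camp$co2_ppm)
  expect_equal(back$timestamp, camp$timestamp)

  atm <- make_linear_atmosphere(2000, 100, 4.7, 25)
  fl <- simulate_flask(substrate_mix(0.3, 5), atm, 2019, 900)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_flask_table(fl, p2)
  expect_equal(as.data.frame(read_flask_table(p2)), as.data.frame(fl))
})
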