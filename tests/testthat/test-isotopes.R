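test_that("Davidson correction matches hand evaluation and its algebraic limits", {
  expect_equal(davidson_correct(1000, -20), -31.59432, tolerance = 1e-6)
  # Ca = 0: the formula collapses to (delta_s - 4.4)/1.0044
  expect_equal(davidson_correct(800, -20, ca_ppm = 0), (-20 - 4.4) / 1.0044)
  # monotone approach to the same limit as the flask saturates with respired CO2
  lim <- (-20 - 4.4) / 1.0044
  cs <- c(800, 2000, 10000, 1e6)
  vals <- davidson_correct(cs, -20)
  expect_true(all(diff(abs(vals - lim)) < 0))
  expect_equal(vals[4], lim, tolerance = 1e-3)
  expect_error(davidson_correct(350, -20), "exceed ambient")
})

test_that("Davidson correction inverts an exact isotope-ratio mixing oracle", {
  # forward model, independent of the correction formula: respired CO2 enters
  # the flask carrying the steady-state diffusive enrichment (factor 1.0044,
  # shift +4.4 permil) and mixes with ambient air by exact molar 13C/12C
  # bookkeeping, not by the linear delta approximation
  r_vpdb <- 0.0112372
  to_ratio <- function(d) (d / 1000 + 1) * r_vpdb
  to_delta <- function(r) (r / r_vpdb - 1) * 1000
  ca <- 400; da <- -9
  for (d_resp in c(-31.14, -29, -27.11)) {
    d_in <- 1.0044 * d_resp + 4.4
    for (cs in c(800, 1200, 4000)) {
      cr <- cs - ca
      ra <- to_ratio(da); rin <- to_ratio(d_in)
      c13 <- ca * ra / (1 + ra) + cr * rin / (1 + rin)
      c12 <- ca / (1 + ra) + cr / (1 + rin)
      ds <- to_delta(c13 / c12)
      expect_equal(davidson_correct(cs, ds), d_resp, tolerance = 0.05)
    }
  }
})

test_that("mean carbon age inverts the atmospheric decline", {
  atm <- atmosphere_record(c(2015, 2021), c(-2.6, -5.4))
  expect_equal(mean_c_age(-5.4, atm, 2021)$mean_age_years, 0)
  expect_equal(mean_c_age(-5.4 + 4.7, atm, 2021)$mean_age_years, 1)
  expect_equal(mean_c_age(65.6, atm, 2021)$mean_age_years, 15.10638,
               tolerance = 1e-5)
  neg <- mean_c_age(-8, atm, 2021)
  expect_equal(neg$mean_age_years, 0)
  expect_true(neg$clamped)
  expect_error(mean_c_age(10, atm, 1990), "outside")
  # strict monotonicity in the sample signature
  ages <- mean_c_age(seq(-5, 60, by = 5), atm, 2021)$mean_age_years
  expect_true(all(diff(ages) > 0))
})

test_that("age recovery is exact through the flask simulator", {
  atm <- make_linear_atmosphere(1990, 150, 4.7, 40)
  for (a in c(0, 1, 5, 15.1)) {
    fl <- simulate_flask(substrate_mix(f_lipid = 0, age_years = a), atm, 2021, 1200)
    expect_equal(mean_c_age(fl$D14C_permil, atm, 2021)$mean_age_years, a,
                 tolerance = 1e-9)
  }
})

test_that("fossil screening discards samples well below the atmosphere", {
  atm <- atmosphere_record(c(2018, 2020), c(-1.4, -3.4)) # -2.4 at 2019
  samples <- tibble::tibble(
    tree_id = c("a", "b", "c"), treatment = "control", date = 2019,
    cs_ppm = 1000, d13c_permil = -28,
    D14C_permil = c(-10, -5, -2.4))
  kept <- screen_fossil(samples, atm)
  expect_equal(kept$tree_id, c("b", "c")) # -10 < -7.4 discarded, -5 retained
  # absolute reading of the rule: everything below +5 permil goes
  kept_abs <- screen_fossil(samples, atm, mode = "absolute")
  expect_equal(nrow(kept_abs), 0)
})

test_that("two-endmember mixing maps signatures to lipid fractions and RQ", {
  m0 <- mixing_fraction(-27.11)
  expect_equal(m0$f_lipid, 0)
  expect_equal(m0$expected_arq, 1.0)
  m1 <- mixing_fraction(-31.14)
  expect_equal(m1$f_lipid, 1)
  expect_equal(m1$expected_arq, 0.7)
  mh <- mixing_fraction(-29.125)
  expect_equal(mh$f_lipid, 0.5)
  expect_equal(mh$expected_arq, 0.85)
  # out-of-range observations clip with a flag
  lo <- mixing_fraction(-25)
  expect_equal(lo$f_lipid, 0)
  expect_true(lo$out_of_range)
  hi <- mixing_fraction(-33)
  expect_equal(hi$f_lipid, 1)
  expect_true(hi$out_of_range)
  expect_error(mixing_fraction(-29, -28, -28), "differ")
})

test_that("substrate fractions round-trip through the flask simulator", {
  atm <- make_linear_atmosphere(2000, 100, 4.7, 25)
  for (f in seq(0, 1, by = 0.25)) {
    fl <- simulate_flask(substrate_mix(f_lipid = f), atm, 2019, 1200)
    expect_equal(mixing_fraction(fl$d13c_permil)$f_lipid, f, tolerance = 1e-9)
  }
})
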