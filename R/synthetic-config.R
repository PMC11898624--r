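#' Simulation configuration for the chamber headspace forward model
#'
#' Defines the "true" state of the simulated stem and sensors: the CO2 efflux
#' at the stem surface, the respiratory quotient that couples O2 uptake to
#' CO2 release, the evaporative water input that humidifies the chamber, the
#' sensor noise levels, an optional linear CO2-sensor drift, and the cycle
#' timing (45 min closed / 15 min flush, samples every 10 s).
#'
#' Defaults emulate a mid-season poplar stem: an efflux of 2 umol m-2 s-1, a
#' mixed-substrate respiratory quotient of 0.85, moderate evaporative
#' humidification, and ~2 ppm sensor noise on both gases.
#'
#' @param resp_flux CO2 efflux at the stem surface, umol m-2 s-1 (> 0).
#' @param rq_true True respiratory quotient (mol CO2 released per mol O2
#'   consumed), in \[0.4, 1.3\].
#' @param evap_rate Water vapor addition from the enclosed stem surface,
#'   umol m-2 s-1 (>= 0); capped at saturation via the Magnus relation.
#' @param noise_sd_co2,noise_sd_o2 Gaussian sensor noise SD, ppm (>= 0).
#' @param drift_ppm_per_day Linear CO2-sensor drift applied across a campaign.
#' @param cycle_closed_s,cycle_flush_s,sample_interval_s Cycle timing in
#'   seconds; closed and flush durations must be multiples of the sampling
#'   interval.
#' @param seed Integer seed controlling all simulator randomness.
#' @param diel_temp Length-2 numeric: mean and amplitude (degrees C) of the
#'   sinusoidal diel air-temperature cycle used by [simulate_campaign()].
#'
#' @return A validated list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(resp_flux = 2, rq_true = 1, noise_sd_co2 = 0)
#' @export
simulation_config <- function(resp_flux = 2,
                              rq_true = 0.85,
                              evap_rate = 2,
                              noise_sd_co2 = 2,
                              noise_sd_o2 = 2,
                              drift_ppm_per_day = 0,
                              cycle_closed_s = 2700,
                              cycle_flush_s = 900,
                              sample_interval_s = 10,
                              seed = 1L,
                              diel_temp = c(15, 5)) {
  stopifnot(is.numeric(resp_flux), length(resp_flux) == 1, resp_flux > 0)
  if (!is.numeric(rq_true) || length(rq_true) != 1 || rq_true < 0.4 || rq_true > 1.3)
    stop("`rq_true` must be a single value in [0.4, 1.3]", call. = FALSE)
  stopifnot(evap_rate >= 0, noise_sd_co2 >= 0, noise_sd_o2 >= 0,
            cycle_closed_s > 0, cycle_flush_s > 0, sample_interval_s > 0,
            length(diel_temp) == 2, diel_temp[2] >= 0)
  if (cycle_closed_s %% sample_interval_s != 0 ||
      cycle_flush_s %% sample_interval_s != 0)
    stop("cycle durations must be multiples of `sample_interval_s`", call. = FALSE)
  structure(
    list(resp_flux = resp_flux, rq_true = rq_true, evap_rate = evap_rate,
         noise_sd_co2 = noise_sd_co2, noise_sd_o2 = noise_sd_o2,
         drift_ppm_per_day = drift_ppm_per_day,
         cycle_closed_s = cycle_closed_s, cycle_flush_s = cycle_flush_s,
         sample_interval_s = sample_interval_s, seed = as.integer(seed),
         diel_temp = as.numeric(diel_temp)),
    class = "simulation_config"
  )
}

#' Chamber geometry and identity
#'
#' @param volume_cm3 Headspace volume, cm^3; the instrument design spans
#'   roughly 50-150 cm^3 (field chambers: 70-105 cm^3).
#' @param area_m2 Enclosed stem surface area, m^2 (field value 0.0028 m^2).
#' @param tree_id Tree label.
#' @param treatment `"control"` or `"girdled"`.
#'
#' @return A validated list of class `chamber_spec`.
#' @examples
#' chamber_spec(volume_cm3 = 100, tree_id = "T1")
#' @export
chamber_spec <- function(volume_cm3 = 100, area_m2 = 0.0028,
                         tree_id = "T1", treatment = c("control", "girdled")) {
  treatment <- match.arg(treatment)
  if (!is.numeric(volume_cm3) || volume_cm3 < 50 || volume_cm3 > 150)
    stop("`volume_cm3` must lie in [50, 150]", call. = FALSE)
  stopifnot(is.numeric(area_m2), area_m2 > 0)
  structure(
    list(volume_cm3 = volume_cm3, area_m2 = area_m2,
         tree_id = as.character(tree_id), treatment = treatment),
    class = "chamber_spec"
  )
}

#' Environmental state at the chamber
#'
#' @param temp_C Air temperature, degrees C (within -30 to 50).
#' @param pressure_kPa Barometric pressure, kPa (> 0).
#' @param rh_pct Relative humidity, percent (0-100).
#'
#' @return A validated list of class `env_state`.
#' @examples
#' env_state(temp_C = 20, pressure_kPa = 101.325, rh_pct = 60)
#' @export
env_state <- function(temp_C = 15, pressure_kPa = 95, rh_pct = 70) {
  stopifnot(pressure_kPa > 0, rh_pct >= 0, rh_pct <= 100,
            temp_C >= -30, temp_C <= 50)
  structure(
    list(temp_C = temp_C, pressure_kPa = pressure_kPa, rh_pct = rh_pct),
    class = "env_state"
  )
}

#' Respiratory substrate mixture
#'
#' Describes the carbon respired in a flask incubation: the fraction drawn
#' from neutral lipids versus soluble sugars, the mean time since that carbon
#' was fixed from the atmosphere, and the endmember \eqn{\delta^{13}C}
#' signatures (field defaults: -27.11 permil for soluble sugars, -31.14
#' permil for neutral lipids).
#'
#' @param f_lipid Fraction of respired carbon from lipids, in \[0, 1\].
#' @param age_years Mean time since fixation, years (>= 0).
#' @param d13c_carb,d13c_lipid Endmember signatures, permil.
#'
#' @return A validated list of class `substrate_mix`.
#' @examples
#' substrate_mix(f_lipid = 0.5, age_years = 5)
#' @export
substrate_mix <- function(f_lipid = 0, age_years = 0,
                          d13c_carb = -27.11, d13c_lipid = -31.14) {
  stopifnot(f_lipid >= 0, f_lipid <= 1, age_years >= 0)
  structure(
    list(f_lipid = f_lipid, age_years = age_years,
         d13c_carb = d13c_carb, d13c_lipid = d13c_lipid),
    class = "substrate_mix"
  )
}
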