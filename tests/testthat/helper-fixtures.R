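# shared fixtures: a standard field chamber, lab-like environment, and
# noise-free simulator settings used across module tests

std_chamber <- function(tree_id = "T1", treatment = "control") {
  chamber_spec(volume_cm3 = 100, area_m2 = 0.0028,
               tree_id = tree_id, treatment = treatment)
}

std_env <- function() env_state(temp_C = 20, pressure_kPa = 101.325, rh_pct = 50)

noise_free_config <- function(...) {
  simulation_config(noise_sd_co2 = 0, noise_sd_o2 = 0, ...)
}

# headspace air amount (umol) implied by the ideal gas law
headspace_umol <- function(chamber, env, constants = phys_constants()) {
  env$pressure_kPa * chamber$volume_cm3 * 1e-6 /
    (constants$R_gas * (env$temp_C + 273.15)) * 1e6
}
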