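#' Simulate a flask incubation sample
#'
#' Generates the isotopic composition of CO2 respired from a known substrate
#' mixture: \eqn{\delta^{13}C} is the flux-weighted linear mixture of the
#' lipid and carbohydrate endmember signatures (endmember signatures are
#' inherited without kinetic fractionation), and \eqn{\Delta^{14}C} is the
#' atmospheric value of the fixation year (`sampling_year - age_years`);
#' radioactive decay over the few decades involved is negligible (< 0.7
#' permil over 60 years) and ignored.
#'
#' @param mix A [substrate_mix()].
#' @param atmosphere An [atmosphere_record()] covering the fixation year.
#' @param sampling_year Decimal year of sampling.
#' @param accumulated_co2_ppm CO2 concentration accumulated in the flask,
#'   ppm.
#' @param tree_id,treatment Sample labels.
#'
#' @return A one-row tibble (flask sample): `tree_id`, `treatment`, `date`
#'   (decimal year), `cs_ppm`, `d13c_permil`, `D14C_permil`.
#' @examples
#' atm <- make_linear_atmosphere(2000, 100, 4.7, 30)
#' simulate_flask(substrate_mix(f_lipid = 0.5, age_years = 5), atm, 2018, 1200)
#' @export
simulate_flask <- function(mix, atmosphere, sampling_year, accumulated_co2_ppm,
                           tree_id = "T1", treatment = "control") {
  stopifnot(inherits(mix, "substrate_mix"), accumulated_co2_ppm > 0)
  fixation_year <- sampling_year - mix$age_years
  d14c <- atm_lookup(atmosphere, fixation_year)
  d13c <- mix$f_lipid * mix$d13c_lipid + (1 - mix$f_lipid) * mix$d13c_carb
  tibble(tree_id = as.character(tree_id), treatment = as.character(treatment),
         date = sampling_year, cs_ppm = accumulated_co2_ppm,
         d13c_permil = d13c, D14C_permil = d14c)
}
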