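#' Physical and method constants
#'
#' Bundle of the constants used throughout the pipeline: the molar gas
#' constant in chamber-friendly units, the Davidson-correction fractionation
#' constants, the mean annual decline of atmospheric bomb \eqn{\Delta^{14}C},
#' assumed ambient-air CO2 concentration and \eqn{\delta^{13}C}, and the
#' canonical respiratory quotients of the two substrate endmembers
#' (carbohydrate ~ 1, lipid ~ 0.7).
#'
#' @param R_gas Molar gas constant, m^3 kPa K^-1 mol^-1.
#' @param davidson_shift Additive fractionation constant of the Davidson
#'   correction, permil.
#' @param davidson_factor Multiplicative fractionation factor of the Davidson
#'   correction (dimensionless).
#' @param atm_decline Mean annual decline of atmospheric \eqn{\Delta^{14}C},
#'   permil per year.
#' @param ca_default Assumed ambient CO2 concentration, ppm.
#' @param da_default Assumed ambient \eqn{\delta^{13}C}, permil.
#' @param rq_carb Respiratory quotient of pure carbohydrate respiration.
#' @param rq_lipid Respiratory quotient of pure lipid respiration.
#'
#' @return A named list of class `phys_constants`.
#' @examples
#' phys_constants()$R_gas
#' @export
phys_constants <- function(R_gas = 0.008314,
                           davidson_shift = 4.4,
                           davidson_factor = 1.0044,
                           atm_decline = 4.7,
                           ca_default = 400,
                           da_default = -9,
                           rq_carb = 1.0,
                           rq_lipid = 0.7) {
  stopifnot(R_gas > 0, davidson_factor > 0, atm_decline > 0,
            ca_default > 0, rq_carb > 0, rq_lipid > 0)
  structure(
    list(R_gas = R_gas, davidson_shift = davidson_shift,
         davidson_factor = davidson_factor, atm_decline = atm_decline,
         ca_default = ca_default, da_default = da_default,
         rq_carb = rq_carb, rq_lipid = rq_lipid),
    class = "phys_constants"
  )
}

# ambient (flush) air composition used by the simulator unless configured
.ambient_defaults <- function() {
  list(co2_ppm = 400, o2_ppm = 209500, d13c_permil = -9)
}
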