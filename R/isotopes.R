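#' Davidson correction of flask \eqn{\delta^{13}C}
#'
#' A flask incubated on a stem contains a mixture of ambient air and
#' accumulated respired CO2. The Davidson equation recovers the
#' \eqn{\delta^{13}C} of the respired component, accounting for diffusive
#' fractionation (+4.4 permil shift, factor 1.0044):
#' \deqn{\delta = \frac{C_s(\delta_s - 4.4) - C_a(\delta_a - 4.4)}
#'                     {1.0044\,(C_s - C_a)}}
#' where \eqn{C_s, \delta_s} are the flask CO2 concentration and isotopic
#' composition and \eqn{C_a, \delta_a} the ambient values (assumed 400 ppm
#' and -9 permil unless stated).
#'
#' @param cs_ppm Flask CO2 concentration, ppm; must exceed `ca_ppm`.
#' @param d13c_raw Flask \eqn{\delta^{13}C}, permil.
#' @param ca_ppm Ambient CO2 concentration, ppm (0 allowed as a limit case).
#' @param da_permil Ambient \eqn{\delta^{13}C}, permil.
#' @param constants A [phys_constants()].
#' @return Corrected \eqn{\delta^{13}C} of respired CO2, permil.
#' @examples
#' davidson_correct(1000, -20) # -31.59 permil
#' @export
davidson_correct <- function(cs_ppm, d13c_raw,
                             ca_ppm = phys_constants()$ca_default,
                             da_permil = phys_constants()$da_default,
                             constants = phys_constants()) {
  if (any(cs_ppm <= ca_ppm))
    stop("flask CO2 must exceed ambient CO2 (no respired accumulation)",
         call. = FALSE)
  s <- constants$davidson_shift
  (cs_ppm * (d13c_raw - s) - ca_ppm * (da_permil - s)) /
    (constants$davidson_factor * (cs_ppm - ca_ppm))
}

#' Mean age of respired carbon from bomb radiocarbon
#'
#' On the declining limb of the atmospheric bomb curve, CO2 respired from
#' older carbon carries a higher \eqn{\Delta^{14}C} than the current
#' atmosphere; dividing the offset by the mean annual decline (4.7 permil
#' per year) dates the mean fixation year:
#' \deqn{\mathrm{age} = \frac{\Delta^{14}C_{sample} -
#'   \Delta^{14}C_{atmosphere}}{4.7}}
#' Small negative ages (sample marginally below the atmosphere, within
#' measurement noise) are clamped to 0 and flagged.
#'
#' @param D14C_sample Sample \eqn{\Delta^{14}C}, permil.
#' @param atmosphere An [atmosphere_record()].
#' @param sampling_year Decimal year of sampling (within the record).
#' @param annual_decline Mean annual atmospheric decline, permil per year.
#' @return A tibble with `mean_age_years` and `clamped` (TRUE where a
#'   negative raw age was clamped to 0).
#' @examples
#' atm <- atmosphere_record(2021, -5.4)
#' mean_c_age(65.6, atm, 2021)$mean_age_years # 15.1 years
#' @export
mean_c_age <- function(D14C_sample, atmosphere, sampling_year,
                       annual_decline = phys_constants()$atm_decline) {
  atm <- atm_lookup(atmosphere, sampling_year)
  raw <- (D14C_sample - atm) / annual_decline
  tibble(mean_age_years = pmax(raw, 0), clamped = raw < 0)
}

#' Screen out fossil-influenced flask samples
#'
#' Samples with \eqn{\Delta^{14}C} clearly below the contemporary atmosphere
#' reflect admixture of radiocarbon-dead CO2 from local fossil sources and
#' are discarded before age estimation. Two readings of the 5-permil rule
#' are available:
#' * `mode = "relative"` (default): discard samples more than `tolerance`
#'   permil below the atmospheric value at their sampling date.
#' * `mode = "absolute"`: discard samples whose \eqn{\Delta^{14}C} is below
#'   `tolerance` permil on the absolute scale.
#'
#' @param samples Flask-sample tibble with columns `D14C_permil` and `date`.
#' @param atmosphere An [atmosphere_record()].
#' @param tolerance Screening threshold, permil.
#' @param mode `"relative"` or `"absolute"`.
#' @return The retained rows of `samples`, unmodified.
#' @export
screen_fossil <- function(samples, atmosphere, tolerance = 5,
                          mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(all(c("D14C_permil", "date") %in% names(samples)))
  keep <- if (mode == "relative") {
    samples$D14C_permil >= atm_lookup(atmosphere, samples$date) - tolerance
  } else {
    samples$D14C_permil >= tolerance
  }
  samples[keep, , drop = FALSE]
}

#' Two-endmember substrate mixing from \eqn{\delta^{13}C}
#'
#' Inverts the linear carbohydrate/lipid mixing model: with soluble sugars
#' at -27.11 permil and neutral lipids at -31.14 permil, an observed
#' respired \eqn{\delta^{13}C} maps to a lipid-derived carbon fraction
#' \deqn{f_{lipid} = \frac{\delta_{obs} - \delta_{carb}}
#'                        {\delta_{lipid} - \delta_{carb}}}
#' (clipped to \[0, 1\] with an out-of-range flag), and to the expected
#' apparent respiratory quotient under substrate stoichiometry,
#' `rq_carb - (rq_carb - rq_lipid) * f_lipid` (1.0 for pure carbohydrate,
#' 0.7 for pure lipid).
#'
#' @param d13c_obs Observed (source-corrected) \eqn{\delta^{13}C}, permil.
#' @param d13c_carb,d13c_lipid Endmember signatures, permil (must differ).
#' @param constants A [phys_constants()] supplying the endmember respiratory
#'   quotients.
#' @return A tibble with `f_lipid`, `expected_arq` and `out_of_range`.
#' @examples
#' mixing_fraction(-29.125)$f_lipid # 0.5
#' @export
mixing_fraction <- function(d13c_obs, d13c_carb = -27.11, d13c_lipid = -31.14,
                            constants = phys_constants()) {
  if (d13c_carb == d13c_lipid)
    stop("endmember signatures must differ", call. = FALSE)
  f_raw <- (d13c_obs - d13c_carb) / (d13c_lipid - d13c_carb)
  f <- pmin(pmax(f_raw, 0), 1)
  tibble(f_lipid = f,
         expected_arq = constants$rq_carb -
           (constants$rq_carb - constants$rq_lipid) * f,
         out_of_range = f_raw < 0 | f_raw > 1)
}
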