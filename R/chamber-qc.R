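#' Saturation vapor pressure over water (Magnus formula)
#'
#' WMO-form Magnus coefficients: 6.112 hPa, 17.62, 243.12 degrees C.
#'
#' @param temp_C Air temperature, degrees C.
#' @return Saturation vapor pressure, hPa.
#' @examples
#' e_sat_hPa(20) # ~23.33 hPa
#' @export
e_sat_hPa <- function(temp_C) {
  6.112 * exp(17.62 * temp_C / (243.12 + temp_C))
}

#' Convert relative humidity to a water vapor mole fraction
#'
#' Relative humidity is converted to vapor pressure via the Magnus formula
#' and divided by total pressure to give the water vapor mole fraction in
#' ppm, the form needed for the non-trace-gas dilution correction of O2.
#'
#' @param rh_pct Relative humidity, percent (0-100).
#' @param temp_C Air temperature, degrees C.
#' @param pressure_kPa Barometric pressure, kPa; must exceed the saturation
#'   vapor pressure.
#' @return Water vapor mole fraction, ppm.
#' @examples
#' rh_to_h2o(50, 20, 101.325) # ~11,500 ppm
#' @export
rh_to_h2o <- function(rh_pct, temp_C, pressure_kPa) {
  if (any(rh_pct < 0, na.rm = TRUE)) stop("negative relative humidity", call. = FALSE)
  if (any(pressure_kPa <= 0, na.rm = TRUE)) stop("nonpositive pressure", call. = FALSE)
  e_sat <- e_sat_hPa(temp_C)            # hPa
  p_hPa <- 10 * pressure_kPa
  if (any(p_hPa <= e_sat, na.rm = TRUE))
    stop("pressure must exceed the saturation vapor pressure", call. = FALSE)
  (rh_pct / 100) * e_sat / p_hPa * 1e6
}

#' Dilution-correct measured O2 mole fractions
#'
#' O2, unlike CO2, is a non-trace gas: when water vapor evaporates into the
#' chamber headspace or CO2 accumulates, the measured (wet) O2 mole fraction
#' changes even without any O2 exchange. Two corrections are offered:
#'
#' * `method = "inert"` (default): O2 is referenced to the inert balance of
#'   the air (N2 + Ar), which is conserved in a closed chamber, and rescaled
#'   to the composition of a reference sample (by default the first):
#'   `o2_corr = o2_wet * inert(ref) / inert(t)` with
#'   `inert = 1e6 - o2_wet - h2o - co2`. Changes in the corrected series then
#'   reflect only O2 exchange: the slope of `o2_corr` equals the molar O2
#'   exchange rate divided by the headspace air amount at the reference
#'   sample, exactly, so the slope ratio of CO2 to corrected O2 recovers the
#'   true respiratory quotient.
#' * `method = "ratio"`: the simple rescaling to a H2O- and CO2-free matrix,
#'   `o2_wet / (1 - (h2o + co2)/1e6)`. This removes the bulk H2O/CO2 dilution
#'   from the level of the series but does not compensate the cross term
#'   between the large O2 mole fraction and the accumulating CO2, and so
#'   biases slope ratios; it is retained for comparison.
#'
#' @param o2_ppm_wet Measured (wet) O2 mole fraction, ppm.
#' @param h2o_ppm Water vapor mole fraction, ppm (from [rh_to_h2o()]).
#' @param co2_ppm Measured CO2 mole fraction, ppm.
#' @param method `"inert"` or `"ratio"`.
#' @param ref Index of the reference sample for `method = "inert"`.
#' @return Corrected O2 series, ppm (same length as the input).
#' @examples
#' dilution_correct_o2(209000, 20000, 1000, method = "ratio") # 213,483 ppm
#' @export
dilution_correct_o2 <- function(o2_ppm_wet, h2o_ppm, co2_ppm,
                                method = c("inert", "ratio"), ref = 1L) {
  method <- match.arg(method)
  n <- length(o2_ppm_wet)
  stopifnot(length(h2o_ppm) %in% c(1L, n), length(co2_ppm) %in% c(1L, n))
  if (any(h2o_ppm + co2_ppm >= 1e6, na.rm = TRUE))
    stop("h2o + co2 must be below 1e6 ppm", call. = FALSE)
  if (method == "ratio") {
    denom <- 1 - (h2o_ppm + co2_ppm) / 1e6
    if (any(denom <= 0, na.rm = TRUE)) stop("nonpositive denominator", call. = FALSE)
    return(o2_ppm_wet / denom)
  }
  inert <- 1e6 - o2_ppm_wet - h2o_ppm - co2_ppm
  if (any(inert <= 0, na.rm = TRUE))
    stop("inert fraction must be positive", call. = FALSE)
  o2_ppm_wet * inert[[ref]] / inert
}

#' Extract the regression fit window from a raw cycle
#'
#' Of each 45-min closed period, the first 5 min after flushing are dropped
#' (pressure perturbations from valve switching) and the following 20 min
#' are used for the regression: samples with `300 <= t_s < 1500` s, i.e. 120
#' points at the 10-s cadence.
#'
#' @param cycle A raw-cycle tibble with at least a `t_s` column (seconds
#'   since closure).
#' @param start_s,end_s Window bounds in seconds; half-open `[start_s, end_s)`.
#' @return The subset of `cycle` rows inside the window.
#' @examples
#' cyc <- simulate_cycle(simulation_config(), chamber_spec(), env_state())
#' nrow(extract_fit_window(cyc)) # 120
#' @export
extract_fit_window <- function(cycle, start_s = 300, end_s = 1500) {
  stopifnot(is.data.frame(cycle), "t_s" %in% names(cycle))
  if (max(cycle$t_s) < end_s - min(diff(sort(unique(cycle$t_s)))))
    stop("cycle too short for the fit window (needs >= 25 min)", call. = FALSE)
  cycle[cycle$t_s >= start_s & cycle$t_s < end_s, , drop = FALSE]
}

#' Ordinary least-squares slope of concentration on time
#'
#' Closed-form OLS fit of a gas concentration series against time, with the
#' coefficient of determination taken as the squared Pearson correlation.
#' A constant concentration series (r2 undefined) is reported as slope 0,
#' r2 = 0, which downstream QC then rejects.
#'
#' @param t_s Time, s.
#' @param conc_ppm Concentration, ppm.
#' @return A list of class `slope_fit`: `slope_ppm_s`, `intercept_ppm`, `r2`,
#'   `n_points`.
#' @examples
#' fit_slope(0:99, 400 + 0.05 * (0:99))
#' @export
fit_slope <- function(t_s, conc_ppm) {
  keep <- complete.cases(t_s, conc_ppm)
  t_s <- t_s[keep]; conc_ppm <- conc_ppm[keep]
  if (length(t_s) < 3) stop("need at least 3 points", call. = FALSE)
  if (var(t_s) == 0) stop("time values are constant", call. = FALSE)
  slope <- cov(t_s, conc_ppm) / var(t_s)
  intercept <- mean(conc_ppm) - slope * mean(t_s)
  r2 <- if (var(conc_ppm) == 0) 0 else cor(t_s, conc_ppm)^2
  structure(
    list(slope_ppm_s = slope, intercept_ppm = intercept,
         r2 = r2, n_points = length(t_s)),
    class = "slope_fit"
  )
}

#' Quality-control flags for one measurement cycle
#'
#' A cycle is retained only if the regressions of both gases are tight
#' (r2 at or above the threshold, default 0.96), the chamber did not
#' approach saturation (mean relative humidity over the fit window at or
#' below 99 percent), and the slopes have the physiological signs (CO2
#' rising, corrected O2 falling).
#'
#' @param fit_co2,fit_o2 `slope_fit` objects for CO2 and dilution-corrected
#'   O2.
#' @param rh_window_pct Mean relative humidity over the fit window, percent.
#' @param r2_min r2 acceptance threshold (set to 0 to retain all cycles).
#' @param rh_max Relative humidity acceptance threshold, percent.
#' @return A list of class `qc_result` with logical fields `pass_r2_co2`,
#'   `pass_r2_o2`, `pass_rh`, `pass_sign`, `overall`.
#' @examples
#' f1 <- fit_slope(0:99, 400 + 0.05 * (0:99))
#' f2 <- fit_slope(0:99, 209000 - 0.05 * (0:99))
#' qc_flags(f1, f2, rh_window_pct = 80)$overall
#' @export
qc_flags <- function(fit_co2, fit_o2, rh_window_pct,
                     r2_min = 0.96, rh_max = 99) {
  pass_r2_co2 <- fit_co2$r2 >= r2_min
  pass_r2_o2 <- fit_o2$r2 >= r2_min
  pass_rh <- rh_window_pct <= rh_max
  pass_sign <- fit_co2$slope_ppm_s > 0 && fit_o2$slope_ppm_s < 0
  structure(
    list(pass_r2_co2 = pass_r2_co2, pass_r2_o2 = pass_r2_o2,
         pass_rh = pass_rh, pass_sign = pass_sign,
         overall = pass_r2_co2 && pass_r2_o2 && pass_rh && pass_sign),
    class = "qc_result"
  )
}

#' Fill short gaps in a flux series by linear interpolation
#'
#' Gaps strictly shorter than `max_gap_h` hours are linearly interpolated on
#' the regular cycle grid; longer gaps (and leading/trailing missing values)
#' are left missing. Interpolated points are flagged.
#'
#' @param values Numeric flux/ARQ series on a regular time grid, `NA` for
#'   missing cycles.
#' @param dt_h Grid spacing, hours (default 1: one 45+15-min cycle).
#' @param max_gap_h Maximum gap duration not considered a data gap, hours.
#' @return A tibble with columns `value` (filled series) and `interpolated`.
#' @examples
#' fill_gaps(c(2, NA, 3))$value # midpoint 2.5
#' @export
fill_gaps <- function(values, dt_h = 1, max_gap_h = 2) {
  stopifnot(dt_h > 0, max_gap_h > 0)
  # gap of k missing points spans k*dt_h hours; fill only if strictly < max_gap_h
  maxgap <- ceiling(max_gap_h / dt_h) - 1L
  filled <- if (maxgap >= 1L) {
    as.numeric(zoo::na.approx(values, maxgap = maxgap, na.rm = FALSE))
  } else {
    values
  }
  tibble(value = filled, interpolated = is.na(values) & !is.na(filled))
}
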