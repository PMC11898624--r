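#' Closed-chamber flux from a concentration slope
#'
#' Ideal-gas closed-chamber flux equation:
#' \deqn{F = \frac{\Delta C}{\Delta t}\times\frac{V}{A}\times\frac{P}{R\,T}}
#' with the slope in ppm s-1 (absolute value), chamber volume V (m^3),
#' enclosed stem area A (m^2), pressure P (kPa), the molar gas constant
#' R = 0.008314 m^3 kPa K-1 mol-1 and temperature T (K). The result is in
#' umol m-2 s-1.
#'
#' @param slope_ppm_s Concentration slope, ppm s-1 (sign ignored).
#' @param chamber A [chamber_spec()].
#' @param env An [env_state()] giving fit-window mean pressure and
#'   temperature.
#' @param constants A [phys_constants()].
#' @return Flux magnitude, umol m-2 s-1.
#' @examples
#' compute_flux(0.05, chamber_spec(100, 0.0028), env_state(20, 101.325, 50))
#' # ~0.0742 umol m-2 s-1
#' @export
compute_flux <- function(slope_ppm_s, chamber, env,
                         constants = phys_constants()) {
  stopifnot(inherits(chamber, "chamber_spec"), inherits(env, "env_state"))
  T_K <- env$temp_C + 273.15
  if (T_K <= 0 || env$pressure_kPa <= 0 || chamber$volume_cm3 <= 0 ||
      chamber$area_m2 <= 0)
    stop("V, A, P and T must be positive", call. = FALSE)
  abs(slope_ppm_s) * (chamber$volume_cm3 * 1e-6 / chamber$area_m2) *
    env$pressure_kPa / (constants$R_gas * T_K)
}

#' Apparent respiratory quotient from paired slopes
#'
#' `ARQ = slope_CO2 / (-slope_O2_corrected)`; the chamber geometry, pressure
#' and temperature terms of the flux equation cancel in the ratio. Defined
#' only when the corrected O2 slope is negative (O2 being consumed);
#' otherwise `NA` is returned and the cycle should be flagged.
#'
#' @param slope_co2 CO2 slope, ppm s-1.
#' @param slope_o2_corr Dilution-corrected O2 slope, ppm s-1 (negative when
#'   O2 is consumed).
#' @return ARQ (dimensionless) or `NA` where undefined.
#' @examples
#' compute_arq(0.05, -0.0625) # 0.8
#' @export
compute_arq <- function(slope_co2, slope_o2_corr) {
  ifelse(slope_o2_corr < 0, slope_co2 / (-slope_o2_corr), NA_real_)
}

#' Tukey-fence retention mask for ARQ values
#'
#' Retains values inside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with quartiles by
#' linear interpolation (`stats::quantile` type 7). With fewer than 4 values
#' the quartiles are not meaningful and everything is retained with a
#' warning.
#'
#' @param values Numeric vector (NAs are never retained).
#' @return Logical vector: TRUE where the value is retained.
#' @export
iqr_keep <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4) {
    warning("fewer than 4 values: IQR filter passed through", call. = FALSE)
    return(ok)
  }
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  ok & values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
}

#' Interquartile-range outlier filter
#'
#' @param values Numeric vector.
#' @return The retained values (see [iqr_keep()] for the rule).
#' @examples
#' iqr_filter(c(0.6, 0.7, 0.75, 0.8, 0.85, 0.9, 2.0)) # drops 2.0
#' @export
iqr_filter <- function(values) {
  values[iqr_keep(values)]
}

#' Aggregate cycle-level fluxes to 6-h and daily means
#'
#' Cycle-level records are averaged in 6-h bins aligned at 00/06/12/18 local
#' time, per tree and treatment. A daily mean is emitted only for calendar
#' days where all four 6-h bins contain data (complete-24-h rule); incomplete
#' days are dropped.
#'
#' @param records Tibble with columns `time` (POSIXct), `tree_id`,
#'   `treatment` and the value columns `e_co2`, `i_o2`, `arq` (NAs are
#'   ignored within bins).
#' @return A list with tibbles `six_hour` (tree_id, treatment, bin_start,
#'   mean of each value column) and `daily` (tree_id, treatment, day, means;
#'   complete days only).
#' @export
aggregate_fluxes <- function(records) {
  stopifnot(all(c("time", "tree_id", "treatment") %in% names(records)))
  vals <- intersect(c("e_co2", "i_o2", "arq"), names(records))
  mean_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }
  binned <- records |>
    dplyr::mutate(
      day = as.Date(.data$time, tz = "UTC"),
      bin = (as.integer(format(.data$time, "%H", tz = "UTC")) %/% 6L) * 6L) |>
    dplyr::group_by(.data$tree_id, .data$treatment, .data$day, .data$bin) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vals), mean_na),
                     n = dplyr::n(), .groups = "drop")

  six_hour <- binned |>
    dplyr::mutate(bin_start = as.POSIXct(.data$day, tz = "UTC") + .data$bin * 3600) |>
    dplyr::select("tree_id", "treatment", "bin_start",
                  dplyr::all_of(vals), "n")

  daily <- records |>
    dplyr::mutate(
      day = as.Date(.data$time, tz = "UTC"),
      bin = (as.integer(format(.data$time, "%H", tz = "UTC")) %/% 6L) * 6L) |>
    dplyr::group_by(.data$tree_id, .data$treatment, .data$day) |>
    dplyr::filter(dplyr::n_distinct(.data$bin[rowSums(
      is.na(dplyr::pick(dplyr::all_of(vals)))) < length(vals)]) == 4L) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vals), mean_na),
                     n = dplyr::n(), .groups = "drop")

  list(six_hour = six_hour, daily = daily)
}
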