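#' Atmospheric bomb-radiocarbon record
#'
#' A record of growing-season atmospheric \eqn{\Delta^{14}C} values (permil)
#' by year, used both to assign fixation-year signatures in the flask
#' simulator and to date respired carbon. Lookups between tabulated years use
#' linear interpolation; annual (growing-season) values are treated as
#' mid-year points on a decimal-year axis.
#'
#' @param year Numeric vector of (decimal) years, strictly increasing.
#' @param d14c_permil Matching \eqn{\Delta^{14}C} values, permil.
#' @return A tibble of class `atmosphere_record` with columns `year`,
#'   `d14c_permil`.
#' @examples
#' atm <- atmosphere_record(2018:2021, c(2.3, -2.4, -3.9, -5.4))
#' atm_lookup(atm, 2019)
#' @export
atmosphere_record <- function(year, d14c_permil) {
  stopifnot(length(year) == length(d14c_permil), length(year) >= 1)
  if (is.unsorted(year, strictly = TRUE))
    stop("`year` must be strictly increasing", call. = FALSE)
  structure(tibble(year = as.numeric(year), d14c_permil = as.numeric(d14c_permil)),
            class = c("atmosphere_record", class(tibble())))
}

#' Look up atmospheric \eqn{\Delta^{14}C} at given years
#'
#' @param atmosphere An [atmosphere_record()].
#' @param year Decimal year(s) to evaluate; must lie within the record.
#' @return \eqn{\Delta^{14}C} values, permil.
#' @export
atm_lookup <- function(atmosphere, year) {
  stopifnot(inherits(atmosphere, "atmosphere_record"))
  rng <- range(atmosphere$year)
  if (any(year < rng[1] | year > rng[2]))
    stop(sprintf("year outside atmospheric record (%.1f-%.1f)", rng[1], rng[2]),
         call. = FALSE)
  if (nrow(atmosphere) == 1) return(rep(atmosphere$d14c_permil, length(year)))
  stats::approx(atmosphere$year, atmosphere$d14c_permil, xout = year)$y
}

#' Construct a linearly declining atmospheric record
#'
#' The post-bomb atmospheric \eqn{\Delta^{14}C} curve declines almost
#' linearly over recent decades (mean annual decline ~4.7 permil per year);
#' this helper builds such an idealized record, e.g. anchored at the 2018
#' growing-season estimate of +2.3 permil.
#'
#' @param start_year First year of the record.
#' @param start_value \eqn{\Delta^{14}C} at `start_year`, permil.
#' @param annual_decline Decline rate, permil per year (>= 0).
#' @param n_years Number of annual entries (>= 1).
#' @return An [atmosphere_record()] with
#'   `value(y) = start_value - annual_decline * (y - start_year)`.
#' @examples
#' atm <- make_linear_atmosphere(2018, 2.3, 4.7, 2)
#' atm_lookup(atm, 2019) # -2.4
#' @export
make_linear_atmosphere <- function(start_year, start_value,
                                   annual_decline = phys_constants()$atm_decline,
                                   n_years = 75) {
  stopifnot(n_years >= 1, annual_decline >= 0)
  years <- start_year + seq_len(n_years) - 1
  atmosphere_record(years, start_value - annual_decline * (years - start_year))
}
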