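#' Write and read sensor-log CSV files
#'
#' The sensor-log schema is one row per 10-s sample: `timestamp_iso`,
#' `tree_id`, `treatment`, `cycle_id`, `t_s`, `co2_ppm`, `o2_ppm_wet`,
#' `rh_pct`, `temp_C`, `pressure_kPa`.
#'
#' @param data Long campaign tibble (see [simulate_campaign()]).
#' @param path CSV path.
#' @return `write_sensor_log` returns `path` invisibly; `read_sensor_log`
#'   returns a tibble with a POSIXct `timestamp` column, ready for
#'   [process_campaign()].
#' @export
write_sensor_log <- function(data, path) {
  out <- dplyr::mutate(data,
    timestamp_iso = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    .keep = "unused", .before = 1L)
  readr::write_csv(dplyr::select(out, "timestamp_iso", "tree_id", "treatment",
                                 "cycle_id", "t_s", "co2_ppm", "o2_ppm_wet",
                                 "rh_pct", "temp_C", "pressure_kPa"), path)
  invisible(path)
}

#' @rdname write_sensor_log
#' @export
read_sensor_log <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::mutate(df,
    timestamp = as.POSIXct(.data$timestamp_iso, tz = "UTC",
                           format = "%Y-%m-%dT%H:%M:%OSZ"),
    .keep = "unused", .before = 1L)
}

#' Write and read flask-sample CSV files
#'
#' Schema: `tree_id`, `treatment`, `date` (decimal year), `cs_ppm`,
#' `d13c_permil`, `D14C_permil`.
#'
#' @param samples Flask-sample tibble (see [simulate_flask()]).
#' @param path CSV path.
#' @return `write_flask_table` returns `path` invisibly; `read_flask_table`
#'   returns the tibble.
#' @export
write_flask_table <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

#' @rdname write_flask_table
#' @export
read_flask_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write and read an atmospheric record CSV (`year`, `d14c_permil`)
#'
#' @param atmosphere An [atmosphere_record()].
#' @param path CSV path.
#' @return `write_atmosphere` returns `path` invisibly; `read_atmosphere`
#'   returns an [atmosphere_record()].
#' @export
write_atmosphere <- function(atmosphere, path) {
  readr::write_csv(as_tibble(atmosphere), path)
  invisible(path)
}

#' @rdname write_atmosphere
#' @export
read_atmosphere <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  atmosphere_record(df$year, df$d14c_permil)
}
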