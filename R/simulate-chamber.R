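#' Simulate one closed-chamber measurement cycle
#'
#' Forward model of the chamber headspace during one closed period. The
#' headspace is treated as well mixed at constant temperature and pressure
#' within the cycle; molar amounts of CO2, O2, H2O and the inert balance
#' (N2 + Ar) are tracked explicitly. Each second the enclosed stem adds
#' `resp_flux * area` umol CO2, removes `resp_flux / rq_true * area` umol O2
#' and adds `evap_rate * area` umol H2O (capped at saturation via the Magnus
#' relation). Reported mole fractions are component over total (wet), so the
#' measured O2 series embeds the dilution effect of accumulating H2O and
#' CO2. Gaussian sensor noise is added to both gas channels; relative
#' humidity is reported noise free.
#'
#' The flush period is assumed to reset the headspace completely to ambient
#' air (400 ppm CO2, 209,500 ppm O2 unless configured via `ambient`), so each
#' cycle starts from ambient composition at the prevailing humidity.
#'
#' @param config A [simulation_config()].
#' @param chamber A [chamber_spec()].
#' @param env An [env_state()].
#' @param start_time Cycle closure time (POSIXct).
#' @param ambient Ambient air composition, a list with `co2_ppm` and
#'   `o2_ppm`.
#' @param drift_offset_ppm Constant offset added to the measured CO2 channel
#'   (used by [simulate_campaign()] to apply sensor drift).
#' @param seed Integer seed; defaults to `config$seed`. Use `NULL` to draw
#'   from the current RNG stream (as [simulate_campaign()] does).
#'
#' @return A tibble (one row per 10-s sample) with columns `t_s`, `co2_ppm`,
#'   `o2_ppm_wet`, `rh_pct`, `temp_C`, `pressure_kPa`, and attributes
#'   `chamber`, `start_time` and `truth` (noise-free molar bookkeeping in
#'   umol: `n_co2`, `n_o2`, `n_h2o`, `n_inert`, `n_tot`).
#' @examples
#' cyc <- simulate_cycle(simulation_config(noise_sd_co2 = 0, noise_sd_o2 = 0),
#'                       chamber_spec(), env_state())
#' head(cyc)
#' @export
simulate_cycle <- function(config, chamber, env,
                           start_time = as.POSIXct("2018-07-05 00:00:00", tz = "UTC"),
                           ambient = .ambient_defaults(),
                           drift_offset_ppm = 0,
                           seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(chamber, "chamber_spec"),
            inherits(env, "env_state"))
  if (is.null(seed)) {
    .simulate_cycle_core(config, chamber, env, start_time, ambient, drift_offset_ppm)
  } else {
    withr::with_seed(seed,
      .simulate_cycle_core(config, chamber, env, start_time, ambient, drift_offset_ppm))
  }
}

.simulate_cycle_core <- function(config, chamber, env, start_time, ambient,
                                 drift_offset_ppm) {
  consts <- phys_constants()
  t_s <- seq(0, config$cycle_closed_s - config$sample_interval_s,
             by = config$sample_interval_s)
  T_K <- env$temp_C + 273.15
  # total headspace amount from the ideal gas law, umol
  n_tot0 <- env$pressure_kPa * (chamber$volume_cm3 * 1e-6) /
    (consts$R_gas * T_K) * 1e6

  x_h2o0 <- rh_to_h2o(env$rh_pct, env$temp_C, env$pressure_kPa) / 1e6
  x_co2_0 <- ambient$co2_ppm / 1e6
  x_o2_0 <- ambient$o2_ppm / 1e6
  x_inert <- 1 - x_co2_0 - x_o2_0 - x_h2o0
  if (x_inert <= 0) stop("ambient composition exceeds unity", call. = FALSE)

  A <- chamber$area_m2
  n_co2 <- x_co2_0 * n_tot0 + config$resp_flux * A * t_s
  n_o2 <- x_o2_0 * n_tot0 - (config$resp_flux / config$rq_true) * A * t_s
  if (any(n_o2 <= 0)) stop("O2 depleted within the cycle", call. = FALSE)
  n_inert <- rep(x_inert * n_tot0, length(t_s))

  # water addition capped so the headspace never exceeds saturation
  x_sat <- e_sat_hPa(env$temp_C) / (10 * env$pressure_kPa)
  n_dry <- n_co2 + n_o2 + n_inert
  n_h2o_raw <- x_h2o0 * n_tot0 + config$evap_rate * A * t_s
  n_h2o <- pmin(n_h2o_raw, x_sat / (1 - x_sat) * n_dry)
  n_tot <- n_dry + n_h2o

  co2_true <- n_co2 / n_tot * 1e6
  o2_true <- n_o2 / n_tot * 1e6
  rh_pct <- pmin(100, (n_h2o / n_tot) * 10 * env$pressure_kPa / e_sat_hPa(env$temp_C) * 100)

  n <- length(t_s)
  out <- tibble(
    t_s = t_s,
    co2_ppm = co2_true + drift_offset_ppm + rnorm(n, 0, config$noise_sd_co2),
    o2_ppm_wet = o2_true + rnorm(n, 0, config$noise_sd_o2),
    rh_pct = rh_pct,
    temp_C = rep(env$temp_C, n),
    pressure_kPa = rep(env$pressure_kPa, n)
  )
  attr(out, "chamber") <- chamber
  attr(out, "start_time") <- start_time
  attr(out, "truth") <- tibble(t_s = t_s, n_co2 = n_co2, n_o2 = n_o2,
                               n_h2o = n_h2o, n_inert = n_inert, n_tot = n_tot)
  out
}

#' Simulate a multi-day chamber campaign
#'
#' Back-to-back 45-min-closed / 15-min-flush cycles over `n_days` for each
#' chamber, with cycle closures on a regular hourly grid. Air temperature
#' follows a sinusoidal diel cycle (`config$diel_temp`, peak at 15:00 local),
#' and the configured linear CO2-sensor drift accumulates with elapsed time.
#' All chambers share one seeded RNG stream, so their noise realizations are
#' mutually independent but the whole campaign is reproducible from
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param chambers List of [chamber_spec()] objects.
#' @param n_days Number of simulated days (>= 1).
#' @param env Baseline [env_state()]; its temperature is the diel mean unless
#'   overridden by `config$diel_temp[1]`.
#' @param start_time Campaign start (first cycle closure, POSIXct).
#'
#' @return A long tibble with one row per sample: `timestamp`, `tree_id`,
#'   `treatment`, `cycle_id`, `t_s`, `co2_ppm`, `o2_ppm_wet`, `rh_pct`,
#'   `temp_C`, `pressure_kPa`. The attribute `truth` is a per-cycle manifest
#'   (cycle_id, tree_id, treatment, start time, resp_flux, rq_true,
#'   temp_C).
#' @examples
#' camp <- simulate_campaign(simulation_config(), list(chamber_spec()), n_days = 1)
#' length(unique(camp$cycle_id)) # 24 cycles per chamber-day
#' @export
simulate_campaign <- function(config, chambers, n_days,
                              env = env_state(),
                              start_time = as.POSIXct("2018-07-05 00:00:00", tz = "UTC")) {
  stopifnot(n_days >= 1, length(chambers) >= 1)
  cycle_s <- config$cycle_closed_s + config$cycle_flush_s
  n_cycles <- floor(n_days * 86400 / cycle_s)

  withr::with_seed(config$seed, {
    rows <- vector("list", n_cycles * length(chambers))
    manifest <- vector("list", n_cycles * length(chambers))
    k <- 0L
    for (ci in seq_along(chambers)) {
      chamber <- chambers[[ci]]
      for (i in seq_len(n_cycles)) {
        elapsed_s <- (i - 1L) * cycle_s
        t0 <- start_time + elapsed_s
        hour <- (elapsed_s / 3600) %% 24
        temp <- config$diel_temp[1] +
          config$diel_temp[2] * sin(2 * pi * (hour - 9) / 24)
        env_i <- env_state(temp_C = temp, pressure_kPa = env$pressure_kPa,
                           rh_pct = env$rh_pct)
        drift <- config$drift_ppm_per_day * elapsed_s / 86400
        cyc <- simulate_cycle(config, chamber, env_i, start_time = t0,
                              drift_offset_ppm = drift, seed = NULL)
        k <- k + 1L
        cycle_id <- sprintf("%s_c%04d", chamber$tree_id, i)
        rows[[k]] <- dplyr::mutate(cyc,
          timestamp = t0 + .data$t_s,
          tree_id = chamber$tree_id,
          treatment = chamber$treatment,
          cycle_id = cycle_id,
          .before = 1L)
        manifest[[k]] <- tibble(
          cycle_id = cycle_id, tree_id = chamber$tree_id,
          treatment = chamber$treatment, start_time = t0,
          resp_flux = config$resp_flux, rq_true = config$rq_true,
          temp_C = temp)
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "truth") <- dplyr::bind_rows(manifest)
    out
  })
}
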