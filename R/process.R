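#' Process one raw cycle into slopes, fluxes and QC flags
#'
#' Runs the full per-cycle chain: fit-window extraction (minutes 5-25),
#' Magnus humidity conversion, non-trace-gas dilution correction of O2 (and,
#' by default, the analogous inert-balance renormalization of CO2, whose
#' effect on the trace gas is minute), closed-form OLS slopes, quality
#' control, the flux equation for CO2 efflux and O2 influx, and the ARQ
#' slope ratio.
#'
#' @param cycle Raw-cycle tibble (columns `t_s`, `co2_ppm`, `o2_ppm_wet`,
#'   `rh_pct`, `temp_C`, `pressure_kPa`).
#' @param chamber A [chamber_spec()]; defaults to the cycle's `chamber`
#'   attribute when present.
#' @param r2_min,rh_max QC thresholds (see [qc_flags()]).
#' @param o2_method Dilution-correction method (see [dilution_correct_o2()]).
#' @param correct_co2 Apply the inert-balance renormalization to CO2 as well
#'   (only meaningful with `o2_method = "inert"`).
#' @param constants A [phys_constants()].
#' @return A one-row tibble: slopes and r2 per gas, fit-window mean RH,
#'   temperature and pressure, `e_co2`, `i_o2` (positive magnitudes,
#'   umol m-2 s-1), `arq`, the QC flags and `qc_overall`.
#' @examples
#' cfg <- simulation_config(noise_sd_co2 = 0, noise_sd_o2 = 0, rq_true = 1)
#' cyc <- simulate_cycle(cfg, chamber_spec(), env_state())
#' process_cycle(cyc)$arq # ~1
#' @export
process_cycle <- function(cycle, chamber = attr(cycle, "chamber"),
                          r2_min = 0.96, rh_max = 99,
                          o2_method = c("inert", "ratio"),
                          correct_co2 = TRUE,
                          constants = phys_constants()) {
  o2_method <- match.arg(o2_method)
  stopifnot(inherits(chamber, "chamber_spec"))
  win <- extract_fit_window(cycle)

  h2o <- rh_to_h2o(win$rh_pct, win$temp_C, win$pressure_kPa)
  o2_corr <- dilution_correct_o2(win$o2_ppm_wet, h2o, win$co2_ppm,
                                 method = o2_method)
  co2_used <- win$co2_ppm
  if (correct_co2 && o2_method == "inert") {
    inert <- 1e6 - win$o2_ppm_wet - h2o - win$co2_ppm
    co2_used <- win$co2_ppm * inert[1] / inert
  }

  fit_co2 <- fit_slope(win$t_s, co2_used)
  fit_o2 <- fit_slope(win$t_s, o2_corr)
  rh_mean <- mean(win$rh_pct)
  qc <- qc_flags(fit_co2, fit_o2, rh_mean, r2_min = r2_min, rh_max = rh_max)

  env <- env_state(temp_C = mean(win$temp_C),
                   pressure_kPa = mean(win$pressure_kPa),
                   rh_pct = min(rh_mean, 100))
  tibble(
    slope_co2 = fit_co2$slope_ppm_s,
    slope_o2_corr = fit_o2$slope_ppm_s,
    r2_co2 = fit_co2$r2,
    r2_o2 = fit_o2$r2,
    rh_mean = rh_mean,
    temp_C = env$temp_C,
    pressure_kPa = env$pressure_kPa,
    e_co2 = compute_flux(fit_co2$slope_ppm_s, chamber, env, constants),
    i_o2 = compute_flux(fit_o2$slope_ppm_s, chamber, env, constants),
    arq = compute_arq(fit_co2$slope_ppm_s, fit_o2$slope_ppm_s),
    pass_r2_co2 = qc$pass_r2_co2,
    pass_r2_o2 = qc$pass_r2_o2,
    pass_rh = qc$pass_rh,
    pass_sign = qc$pass_sign,
    qc_overall = qc$overall
  )
}

#' Process a whole campaign of raw cycles
#'
#' Applies [process_cycle()] to every cycle of a long sensor log (as
#' produced by [simulate_campaign()] or read from a sensor-log CSV). Cycles
#' too short for the fit window are skipped with a warning.
#'
#' @param data Long tibble with columns `timestamp`, `tree_id`, `treatment`,
#'   `cycle_id` plus the raw sensor columns.
#' @param chambers List of [chamber_spec()] objects covering every `tree_id`
#'   in `data`; alternatively a single spec applied to all trees.
#' @param ... Passed on to [process_cycle()].
#' @return Flux-record tibble: one row per cycle with `time` (cycle
#'   closure), identifiers, and all [process_cycle()] columns.
#' @export
process_campaign <- function(data, chambers, ...) {
  need <- c("timestamp", "tree_id", "treatment", "cycle_id", "t_s",
            "co2_ppm", "o2_ppm_wet", "rh_pct", "temp_C", "pressure_kPa")
  stopifnot(all(need %in% names(data)))
  if (inherits(chambers, "chamber_spec")) chambers <- list(chambers)
  by_tree <- stats::setNames(chambers,
                             vapply(chambers, `[[`, character(1), "tree_id"))

  split_idx <- split(seq_len(nrow(data)), data$cycle_id)
  rows <- lapply(names(split_idx), function(cid) {
    cyc <- data[split_idx[[cid]], , drop = FALSE]
    tree <- cyc$tree_id[1]
    chamber <- by_tree[[tree]]
    if (is.null(chamber) && length(by_tree) == 1L) chamber <- by_tree[[1L]]
    if (is.null(chamber))
      stop(sprintf("no chamber spec for tree '%s'", tree), call. = FALSE)
    rec <- tryCatch(process_cycle(cyc, chamber = chamber, ...),
                    error = function(e) {
                      warning(sprintf("cycle '%s' skipped: %s", cid,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (is.null(rec)) return(NULL)
    dplyr::bind_cols(
      tibble(cycle_id = cid, tree_id = tree, treatment = cyc$treatment[1],
             time = min(cyc$timestamp)),
      rec)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$tree_id, .data$time)
}

#' QC-screen, outlier-filter and gap-fill a flux-record table
#'
#' Applies the campaign-level screening used before aggregation: QC-failed
#' cycles are masked, ARQ outliers are removed per group with the Tukey
#' fence ([iqr_keep()]), and gaps shorter than `max_gap_h` in each tree's
#' hourly cycle series are filled by linear interpolation.
#'
#' @param records Output of [process_campaign()].
#' @param iqr_group Column(s) defining the ARQ outlier-screening group
#'   (default per tree).
#' @param max_gap_h Maximum gap to interpolate, hours.
#' @return `records` with masked/filled `e_co2`, `i_o2`, `arq` columns and an
#'   added `interpolated` flag.
#' @export
screen_flux_records <- function(records, iqr_group = "tree_id", max_gap_h = 2) {
  vals <- c("e_co2", "i_o2", "arq")
  rec <- records
  for (v in vals) rec[[v]][!rec$qc_overall] <- NA_real_

  grp <- interaction(rec[iqr_group], drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    keep <- suppressWarnings(iqr_keep(rec$arq[idx]))
    rec$arq[idx[!keep]] <- NA_real_
  }

  rec <- rec[order(rec$tree_id, rec$time), , drop = FALSE]
  rec$interpolated <- FALSE
  for (tr in unique(rec$tree_id)) {
    idx <- which(rec$tree_id == tr)
    dt_h <- if (length(idx) > 1) {
      as.numeric(difftime(rec$time[idx[2]], rec$time[idx[1]], units = "hours"))
    } else 1
    for (v in vals) {
      f <- fill_gaps(rec[[v]][idx], dt_h = dt_h, max_gap_h = max_gap_h)
      rec[[v]][idx] <- f$value
      rec$interpolated[idx] <- rec$interpolated[idx] | f$interpolated
    }
  }
  as_tibble(rec)
}
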