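#' Pipeline run configuration
#'
#' A fully serializable description of an end-to-end synthetic run: the
#' two-treatment campaign (girdling blocks the phloem supply of fresh
#' assimilates, shifting girdled trees toward older, lipid-derived
#' respiratory carbon), the QC thresholds, and the isotope and image stages.
#' Every stochastic step derives its stream from `seed`, so a run is
#' reproducible from `config` alone.
#'
#' @param out_dir Output directory for the run's CSV tables and manifest.
#' @param seed Master seed.
#' @param n_days Campaign length, days.
#' @param n_control,n_girdled Chambers (trees) per treatment.
#' @param volume_cm3,area_m2 Chamber geometry shared by all chambers.
#' @param control,girdled Per-treatment truth: lists with `resp_flux`,
#'   `rq_true`, `f_lipid`, `age_years` (see [simulation_config()] and
#'   [substrate_mix()]).
#' @param evap_rate,noise_sd_co2,noise_sd_o2,diel_temp Shared simulator
#'   settings.
#' @param r2_min,rh_max,o2_method,max_gap_h,iqr_group QC settings (see
#'   [process_cycle()] and [screen_flux_records()]).
#' @param sampling_year Decimal year of the flask sampling campaign.
#' @param atm_start_year,atm_start_value,atm_annual_decline Linear
#'   atmospheric \eqn{\Delta^{14}C} record (see [make_linear_atmosphere()]).
#' @param flask_cs_ppm Accumulated flask CO2, ppm.
#' @param d13c_noise_sd Measurement noise on flask \eqn{\delta^{13}C},
#'   permil.
#' @param d14c_noise_sd Measurement noise on flask \eqn{\Delta^{14}C},
#'   permil.
#' @param run_isotopes,run_images Stage toggles.
#' @param image_coverage_pct Target coverage of the simulated section image.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("stemresp_run_"),
                       seed = 1L,
                       n_days = 5,
                       n_control = 3, n_girdled = 3,
                       volume_cm3 = 100, area_m2 = 0.0028,
                       control = list(resp_flux = 2, rq_true = 1.0,
                                      f_lipid = 0, age_years = 1),
                       girdled = list(resp_flux = 1, rq_true = 0.7,
                                      f_lipid = 1, age_years = 10),
                       evap_rate = 2, noise_sd_co2 = 2, noise_sd_o2 = 2,
                       diel_temp = c(15, 5),
                       r2_min = 0.96, rh_max = 99, o2_method = "inert",
                       max_gap_h = 2, iqr_group = "tree_id",
                       sampling_year = 2019.5,
                       atm_start_year = 1960, atm_start_value = 280,
                       atm_annual_decline = 4.7,
                       flask_cs_ppm = 1200,
                       d13c_noise_sd = 0.3, d14c_noise_sd = 2,
                       run_isotopes = TRUE, run_images = FALSE,
                       image_coverage_pct = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic-campaign pipeline
#'
#' Executes the stages in fixed order — simulate, QC/flux/ARQ, screen and
#' aggregate, isotopes, images, treatment summaries — writing each stage's
#' table as CSV into `config$out_dir` together with a JSON manifest (config
#' hash, seed, package version, file list). Any stage failure aborts with a
#' stage-labeled error and removes the partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory tables (`records`,
#'   `aggregates`, `summaries`, optionally `isotopes`, `coverage`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(tbl, name) {
    p <- file.path(config$out_dir, name)
    readr::write_csv(tbl, p)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  result <- tryCatch({
    make_chambers <- function(n, prefix, treatment)
      lapply(seq_len(n), function(i)
        chamber_spec(config$volume_cm3, config$area_m2,
                     tree_id = sprintf("%s%02d", prefix, i),
                     treatment = treatment))

    stage <- "simulate"
    cfg_of <- function(truth, seed)
      simulation_config(resp_flux = truth$resp_flux, rq_true = truth$rq_true,
                        evap_rate = config$evap_rate,
                        noise_sd_co2 = config$noise_sd_co2,
                        noise_sd_o2 = config$noise_sd_o2,
                        diel_temp = config$diel_temp, seed = seed)
    ctrl_chambers <- make_chambers(config$n_control, "C", "control")
    gird_chambers <- make_chambers(config$n_girdled, "G", "girdled")
    raw <- dplyr::bind_rows(
      simulate_campaign(cfg_of(config$control, config$seed),
                        ctrl_chambers, config$n_days),
      simulate_campaign(cfg_of(config$girdled, config$seed + 1L),
                        gird_chambers, config$n_days))
    write_sensor_log(raw, file.path(config$out_dir, "sensor_log.csv"))
    written <- c(written, file.path(config$out_dir, "sensor_log.csv"))

    stage <- "qc_flux"
    records <- process_campaign(raw, c(ctrl_chambers, gird_chambers),
                                r2_min = config$r2_min, rh_max = config$rh_max,
                                o2_method = config$o2_method)
    records <- screen_flux_records(records, iqr_group = config$iqr_group,
                                   max_gap_h = config$max_gap_h)
    emit(records, "flux_records.csv")

    stage <- "aggregate"
    aggregates <- aggregate_fluxes(records)
    emit(aggregates$six_hour, "flux_6h.csv")
    emit(aggregates$daily, "flux_daily.csv")

    isotopes <- NULL
    if (isTRUE(config$run_isotopes)) {
      stage <- "isotopes"
      atm <- make_linear_atmosphere(config$atm_start_year, config$atm_start_value,
                                    config$atm_annual_decline,
                                    n_years = ceiling(config$sampling_year -
                                                        config$atm_start_year) + 2)
      sim_flasks <- function(truth, chambers, offset) {
        mix <- substrate_mix(f_lipid = truth$f_lipid, age_years = truth$age_years)
        dplyr::bind_rows(lapply(chambers, function(ch)
          simulate_flask(mix, atm, config$sampling_year, config$flask_cs_ppm,
                         tree_id = ch$tree_id, treatment = ch$treatment)))
      }
      flasks <- dplyr::bind_rows(sim_flasks(config$control, ctrl_chambers, 2L),
                                 sim_flasks(config$girdled, gird_chambers, 3L))
      flasks <- withr::with_seed(config$seed + 2L, dplyr::mutate(flasks,
        d13c_permil = .data$d13c_permil +
          rnorm(dplyr::n(), 0, config$d13c_noise_sd),
        D14C_permil = .data$D14C_permil +
          rnorm(dplyr::n(), 0, config$d14c_noise_sd)))
      emit(flasks, "flask_samples.csv")

      retained <- screen_fossil(flasks, atm)
      age <- mean_c_age(retained$D14C_permil, atm, retained$date)
      mixing <- mixing_fraction(retained$d13c_permil)
      isotopes <- dplyr::bind_cols(
        dplyr::select(retained, "tree_id", "treatment", "date", "d13c_permil"),
        age, mixing)
      emit(isotopes, "isotopes.csv")
    }

    coverage <- NULL
    if (isTRUE(config$run_images)) {
      stage <- "images"
      img <- simulate_oro_image(config$image_coverage_pct,
                                seed = config$seed + 4L)
      cov <- roi_coverage(stain_mask(img), img$um_per_px,
                          roi_spec(seed = config$seed + 5L))
      coverage <- tibble(true_coverage_pct = img$true_coverage_pct,
                         mean_coverage_pct = cov$mean_coverage_pct,
                         sd_pct = cov$sd_pct, n_rois = cov$n_rois)
      emit(coverage, "lipid_coverage.csv")
    }

    stage <- "summaries"
    daily <- aggregates$daily
    summaries <- summarize_treatments(daily, group_keys = "treatment",
                                      value_cols = c("e_co2", "i_o2", "arq"))
    if (!is.null(isotopes)) {
      summaries <- dplyr::bind_rows(summaries,
        summarize_treatments(isotopes, group_keys = "treatment",
                             value_cols = c("mean_age_years", "f_lipid",
                                            "expected_arq")))
    }
    emit(summaries, "treatment_summaries.csv")

    stage <- "manifest"
    manifest <- list(
      package = "stemresp",
      version = as.character(utils::packageVersion("stemresp")),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
      files = basename(written))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    list(records = records, aggregates = aggregates, isotopes = isotopes,
         coverage = coverage, summaries = summaries, manifest = manifest)
  }, error = function(e) {
    file.remove(written[file.exists(written)])
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

#' Per-treatment summary statistics
#'
#' Mean and sample SD (n - 1 denominator; 0 when n = 1) of each value column
#' per group, in long format.
#'
#' @param table Value table.
#' @param group_keys Grouping column(s), e.g. `"treatment"`.
#' @param value_cols Value column(s) to summarize.
#' @return Long tibble: group keys, `variable`, `n`, `mean`, `sd`. Groups
#'   with no non-missing values are omitted with a warning.
#' @examples
#' summarize_treatments(tibble::tibble(g = "a", x = c(1, 2, 3)), "g", "x")
#' @export
summarize_treatments <- function(table, group_keys = "treatment", value_cols) {
  stopifnot(nrow(table) > 0, all(c(group_keys, value_cols) %in% names(table)))
  long <- tidyr::pivot_longer(
    dplyr::select(table, dplyr::all_of(c(group_keys, value_cols))),
    cols = dplyr::all_of(value_cols), names_to = "variable")
  out <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_keys, "variable")))) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
                     .groups = "drop")
  n_expected <- nrow(unique(table[group_keys])) * length(value_cols)
  if (nrow(out) < n_expected)
    warning("empty groups omitted from the summary", call. = FALSE)
  out
}

#' Pearson correlation on pairwise-complete observations
#'
#' Signed Pearson r (never a signed r-squared) with the number of complete
#' pairs used.
#'
#' @param x,y Paired numeric series.
#' @return A tibble with `r` and `n`.
#' @examples
#' correlate(1:10, -(1:10))$r # -1
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(x[ok]) == 0 || var(y[ok]) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  tibble(r = cor(x[ok], y[ok]), n = sum(ok))
}
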