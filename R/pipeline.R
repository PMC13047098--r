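#' Enumerate the design: how many models and curves a run will produce
#'
#' Pure arithmetic over the trial design, independent of data values:
#' `fields x timings x VIs` regression models (split by period) and
#' `transects x curve timings x VIs` transect-level response curves.
#'
#' @param n_trials Number of field trials.
#' @param transects_per_trial Transects per trial.
#' @param timings Timing indices entering the regression battery.
#' @param curve_timings Timing indices entering the curve battery.
#' @param vis Vegetation index names.
#' @param timing_calendar Maps timing to period
#'   (default [default_timing_calendar()]).
#' @return List of class `enumeration_report` with counts:
#'   `models_total`, `models_vegetative`, `models_reproductive`,
#'   `curves_total`, `curves_per_trial`, `curves_per_vi`,
#'   `curves_by_group` (tibble), `n_transects`.
#' @export
#' @examples
#' enumerate_design() # the default three-trial design
enumerate_design <- function(n_trials = 3, transects_per_trial = 8,
                             timings = 1:7, curve_timings = 1:3,
                             vis = vi_names(),
                             timing_calendar = default_timing_calendar()) {
  n_vis <- length(vis)
  period <- timing_calendar$period[match(timings, timing_calendar$timing)]
  n_veg <- sum(period == "vegetative", na.rm = TRUE)
  n_rep <- sum(period == "reproductive", na.rm = TRUE)
  n_transects <- n_trials * transects_per_trial
  groups <- vi_definitions()
  groups <- groups[groups$vi_name %in% vis, ]
  curves_by_group <- groups |>
    dplyr::count(.data$group, name = "n_vis") |>
    dplyr::mutate(
      curves_total = .data$n_vis * n_transects * length(curve_timings),
      curves_per_trial = .data$n_vis * transects_per_trial * length(curve_timings)
    )
  structure(list(
    models_total = as.integer(n_trials * length(timings) * n_vis),
    models_vegetative = as.integer(n_trials * n_veg * n_vis),
    models_reproductive = as.integer(n_trials * n_rep * n_vis),
    curves_total = as.integer(n_transects * length(curve_timings) * n_vis),
    curves_per_trial = as.integer(transects_per_trial * length(curve_timings) * n_vis),
    curves_per_vi = as.integer(n_transects * length(curve_timings)),
    curves_by_group = curves_by_group,
    n_transects = n_transects
  ), class = "enumeration_report")
}

#' @export
print.enumeration_report <- function(x, ...) {
  cat("<enumeration_report>\n")
  cat(sprintf("  regression models: %d total (%d vegetative, %d reproductive)\n",
              x$models_total, x$models_vegetative, x$models_reproductive))
  cat(sprintf("  VI-N curves: %d total, %d per trial, %d per VI (%d transects)\n",
              x$curves_total, x$curves_per_trial, x$curves_per_vi, x$n_transects))
  invisible(x)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Simulate the configured trials, render scenes and extract zonal VI
#' means, generate and clean yield-monitor points, fit the regression
#' battery, fit and screen the transect-level response curves, and
#' compute AONR agreement -- a single deterministic, seeded run. If
#' `out_dir` is given, every stage's tables are written as CSV along
#' with an audit JSON and a run log.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param timings Timings for the regression battery (default: full
#'   calendar).
#' @param curve_timings Timings for the curve battery (default 1:3).
#' @param thresholds Cleaning thresholds ([clean_thresholds()]).
#' @param p_threshold Regression significance threshold (default 0.10).
#' @param r2_threshold Curve retention threshold (default 0.50).
#' @param write_scenes Also write every rendered scene as TIFF.
#' @return List of class `aonrvi_run`: `config`, `sims`, `zonal`,
#'   `yields`, `cleaning_audits`, `regressions`, `regression_summary`,
#'   `decisions`, `retention` (overall and by field/timing/VI/group),
#'   `pairs`, `agreement` (overall and grouped), `enumeration`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         timings = config$timings$timing, curve_timings = 1:3,
                         thresholds = clean_thresholds(),
                         p_threshold = 0.10, r2_threshold = 0.50,
                         write_scenes = FALSE) {
  sims <- simulate_trials(config, timings = timings)

  zonal <- purrr::map(sims, function(s) {
    purrr::map(s$scenes, zonal_vi_table, zones = s$design$zones) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()

  cleaned <- purrr::map(sims, function(s) {
    clean_yield(s$yield_points, s$design$subplot_rects, thresholds)
  })
  yields <- purrr::map(cleaned, "subplot_yield") |> purrr::list_rbind()

  regressions <- run_regression_battery(
    zonal, yields, timing_calendar = config$timings,
    timings = timings, p_threshold = p_threshold
  )
  regression_summary <- summarize_battery(regressions)

  designs <- purrr::map(sims, "design")
  decisions <- run_curve_battery(zonal, yields, designs,
                                 timings = curve_timings,
                                 r2_threshold = r2_threshold)
  retention <- list(
    overall = retention_summary(decisions),
    by_field = retention_summary(decisions, "trial_id"),
    by_field_timing = retention_summary(decisions, c("trial_id", "timing")),
    by_vi = retention_summary(decisions, c("vi_group", "vi_name")),
    by_vi_timing = retention_summary(decisions, c("vi_group", "vi_name", "timing")),
    by_group_timing = retention_summary(decisions, c("vi_group", "timing"))
  )

  pairs <- aonr_pairs(decisions)
  agreement <- list(
    overall = agreement_stats(pairs),
    by_field = agreement_stats(pairs, "trial_id"),
    by_group_timing = agreement_stats(pairs, c("vi_group", "timing")),
    by_vi_timing = agreement_stats(pairs, c("vi_group", "vi_name", "timing"))
  )

  enumeration <- enumerate_design(
    n_trials = length(config$trials),
    transects_per_trial = config$transects_per_trial,
    timings = timings, curve_timings = curve_timings,
    timing_calendar = config$timings
  )
  stopifnot(
    enumeration$models_total == nrow(regressions),
    enumeration$curves_total == sum(decisions$vi_name != "yield")
  )

  run <- structure(list(
    config = config, sims = sims, zonal = zonal, yields = yields,
    cleaning_audits = purrr::map(cleaned, "audit"),
    regressions = regressions, regression_summary = regression_summary,
    decisions = decisions, retention = retention,
    pairs = pairs, agreement = agreement, enumeration = enumeration
  ), class = "aonrvi_run")

  if (!is.null(out_dir)) write_run(run, out_dir, write_scenes = write_scenes)
  run
}

#' @export
print.aonrvi_run <- function(x, ...) {
  cat("<aonrvi_run>\n")
  print(x$enumeration)
  ret <- x$retention$overall
  cat(sprintf("  curves retained: %d / %d (%.1f%%)\n",
              ret$n_usable, ret$n_curves, ret$pct_usable))
  ag <- x$agreement$overall
  if (nrow(ag) > 0 && ag$n_pairs > 0) {
    cat(sprintf("  AONR agreement: n = %d pairs, mean %% diff = %.1f, R^2 = %.2f, RMSE = %.1f kg/ha, MAE = %.1f kg/ha\n",
                ag$n_pairs, ag$mean_pct_diff, ag$r_squared, ag$rmse, ag$mae))
  }
  invisible(x)
}

# Write every stage table of a run to disk (CSV + JSON + log).
write_run <- function(run, out_dir, write_scenes = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    write.csv(df, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
  }
  wcsv(run$zonal, "zonal_vi")
  wcsv(run$yields, "subplot_yield")
  wcsv(run$regressions, "regressions")
  wcsv(run$regression_summary, "regression_summary")
  wcsv(run$decisions, "curve_decisions")
  wcsv(run$retention$by_field_timing, "retention_by_field_timing")
  wcsv(run$retention$by_vi_timing, "retention_by_vi_timing")
  wcsv(run$pairs, "aonr_pairs")
  wcsv(run$agreement$by_vi_timing, "agreement_by_vi_timing")
  for (s in run$sims) {
    wcsv(s$yield_points, paste0("yield_points_", s$design$trial_id))
    wcsv(s$design$zones, paste0("zones_", s$design$trial_id))
    if (write_scenes) {
      for (nm in names(s$scenes)) {
        write_scene(s$scenes[[nm]],
                    file.path(out_dir, sprintf("scene_%s_%s.tif",
                                               s$design$trial_id, nm)))
      }
    }
  }
  jsonlite::write_json(
    list(
      enumeration = unclass(run$enumeration)[c(
        "models_total", "models_vegetative", "models_reproductive",
        "curves_total", "curves_per_trial", "curves_per_vi"
      )],
      retention_overall = as.list(run$retention$overall),
      agreement_overall = as.list(run$agreement$overall),
      cleaning = run$cleaning_audits
    ),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  writeLines(c(
    sprintf("aonrvi run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", run$config$seed),
    sprintf("R: %s", R.version.string),
    sprintf("trials: %s",
            paste(vapply(run$config$trials, `[[`, "", "trial_id"), collapse = ", ")),
    sprintf("thresholds: p < %s, R2 > %s", 0.10, 0.50)
  ), file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Read a simulation configuration from a YAML file
#'
#' Overrides the [sim_config()] defaults with whatever scalar fields the
#' YAML document provides (`transects_per_trial`, geometry, noise,
#' `seed`, ...), and rebuilds the trial roster if a `trials` block is
#' present (each entry: `trial_id`, `fnr`, `residue_fraction`,
#' `treatments` with `treatment`/`n_rate` lists, optional AONR
#' distribution).
#'
#' @param path YAML file path.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  doc <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("transects_per_trial", "subplot_length_m", "plot_width_m",
               "buffer_adjacent_m", "buffer_consecutive_m", "pixel_size_m",
               "noise_sd_reflectance", "noise_sd_yield",
               "yield_points_per_subplot", "passes_per_subplot",
               "artifact_fraction", "seed")
  for (s in scalars) if (!is.null(doc[[s]])) args[[s]] <- doc[[s]]
  for (blk in c("yield_model", "canopy")) {
    if (!is.null(doc[[blk]])) {
      merged <- formals(sim_config)[[blk]]
      merged <- utils::modifyList(eval(merged), doc[[blk]])
      args[[blk]] <- merged
    }
  }
  if (!is.null(doc$trials)) {
    args$trials <- lapply(doc$trials, function(tr) {
      list(
        trial_id = tr$trial_id, fnr = tr$fnr,
        residue_fraction = tr$residue_fraction %||% 0.2,
        treatments = tibble::tibble(
          treatment = unlist(tr$treatments$treatment),
          n_rate = as.numeric(unlist(tr$treatments$n_rate))
        ),
        true_aonr_mean = tr$true_aonr_mean %||% (0.8 * tr$fnr),
        true_aonr_sd = tr$true_aonr_sd %||% 25
      )
    })
  }
  do.call(sim_config, args)
}
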