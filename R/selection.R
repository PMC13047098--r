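#' Screen one plateau fit against the selection criteria
#'
#' Screens applied in order: convergence, `R^2 > 0.50` (strict), and
#' agronomic plausibility (positive slope for the linear plateau,
#' concave-down curvature for the quadratic plateau).
#'
#' @param fit A `plateau_fit` (or `NULL`).
#' @param r2_threshold Retention threshold on R-squared (default 0.50).
#' @return `"pass"` or a reason code: `no_convergence`, `low_r2`,
#'   `nonpositive_slope`, `not_concave_down`.
#' @export
screen_plateau_fit <- function(fit, r2_threshold = 0.50) {
  if (is.null(fit) || !isTRUE(fit$converged)) return("no_convergence")
  if (is.na(fit$r_squared) || fit$r_squared <= r2_threshold) return("low_r2")
  if (fit$family == "linear_plateau" && fit$b <= 0) return("nonpositive_slope")
  if (fit$family == "quadratic_plateau" && (!is.finite(fit$c) || fit$c >= 0)) {
    return("not_concave_down")
  }
  "pass"
}

#' Screen two candidate fits and select the response curve
#'
#' Both the linear-plateau and quadratic-plateau candidates are screened
#' with [screen_plateau_fit()]. Among the passers the fit with the lower
#' AIC is selected; an exact AIC tie (absolute difference below
#' `aic_tie_tol`) goes to the quadratic plateau. The selected fit's join
#' point is the candidate AONR; if it exceeds the maximum tested N rate
#' (strictly), the curve is discarded and carries no AONR. A join
#' exactly at the maximum rate is kept.
#'
#' @param lp,qp `plateau_fit` candidates (linear and quadratic plateau).
#' @param max_n_rate Largest N rate tested in the trial (kg/ha).
#' @param r2_threshold Retention threshold on R-squared.
#' @param aic_tie_tol Absolute AIC difference treated as a tie.
#' @return One-row tibble: screening reasons per family, `selected`
#'   family (or `NA`), `aonr_candidate`, `aonr` (kg/ha or `NA`),
#'   `discarded_exceeds_max`, and per-family diagnostics.
#' @export
screen_and_select <- function(lp, qp, max_n_rate,
                              r2_threshold = 0.50, aic_tie_tol = 1e-9) {
  lp_verdict <- screen_plateau_fit(lp, r2_threshold)
  qp_verdict <- screen_plateau_fit(qp, r2_threshold)

  selected <- NA_character_
  if (lp_verdict == "pass" && qp_verdict == "pass") {
    d <- qp$aic - lp$aic
    if (is.nan(d)) d <- 0  # both -Inf: two perfect fits tie
    selected <- if (abs(d) < aic_tie_tol || d < 0) "quadratic_plateau"
                else "linear_plateau"
  } else if (lp_verdict == "pass") {
    selected <- "linear_plateau"
  } else if (qp_verdict == "pass") {
    selected <- "quadratic_plateau"
  }

  aonr_candidate <- NA_real_
  if (!is.na(selected)) {
    aonr_candidate <- if (selected == "linear_plateau") lp$x0 else qp$x0
  }
  discarded <- !is.na(aonr_candidate) && aonr_candidate > max_n_rate
  tibble::tibble(
    lp_verdict = lp_verdict, qp_verdict = qp_verdict,
    lp_r2 = if (is.null(lp)) NA_real_ else lp$r_squared,
    qp_r2 = if (is.null(qp)) NA_real_ else qp$r_squared,
    lp_aic = if (is.null(lp)) NA_real_ else lp$aic,
    qp_aic = if (is.null(qp)) NA_real_ else qp$aic,
    lp_x0 = if (is.null(lp)) NA_real_ else lp$x0,
    qp_x0 = if (is.null(qp)) NA_real_ else qp$x0,
    selected = selected,
    aonr_candidate = aonr_candidate,
    discarded_exceeds_max = discarded,
    aonr = ifelse(discarded || is.na(aonr_candidate), NA_real_, aonr_candidate)
  )
}

fit_and_select <- function(x, y, max_n_rate, r2_threshold = 0.50) {
  lp <- tryCatch(fit_linear_plateau(x, y), error = function(e) NULL)
  qp <- tryCatch(fit_quadratic_plateau(x, y), error = function(e) NULL)
  screen_and_select(lp, qp, max_n_rate, r2_threshold)
}

#' Fit and screen every transect-level N-response curve
#'
#' One decision per (transect, timing, VI) combination for the
#' vegetative timings -- linear- and quadratic-plateau candidates fitted
#' to the five subplot VI means against N rate, screened and selected
#' with [screen_and_select()] -- plus one yield-N decision per transect
#' (`vi_name = "yield"`, `timing = NA`) obtained by the identical
#' procedure on the cleaned subplot yields. Combinations with missing or
#' insufficient data appear as flagged placeholder rows so the
#' enumeration `transects x timings x VIs` is preserved.
#'
#' @param zonal Long zonal VI table (`trial_id`, `transect_id`,
#'   `subplot_id`, `n_rate`, `timing`, `vi_name`, `mean_value`).
#' @param yields Cleaned subplot yields (`trial_id`, `transect_id`,
#'   `subplot_id`, `n_rate`, `yield`).
#' @param designs List of trial designs (for `max_n_rate` and the
#'   transect roster), e.g. `lapply(sims, function(s) s$design)`.
#' @param timings Timings entering VI-N curves (default 1:3, the
#'   vegetative window).
#' @param vis Vegetation indices to enumerate.
#' @param r2_threshold Retention threshold on R-squared.
#' @return Decisions tibble: keys, screening verdicts, selected family,
#'   `aonr`, `discarded_exceeds_max`, `flag`.
#' @export
run_curve_battery <- function(zonal, yields, designs, timings = 1:3,
                              vis = vi_names(), r2_threshold = 0.50) {
  roster <- purrr::map(designs, function(d) {
    tibble::tibble(trial_id = d$trial_id, transect_id = d$transect_ids,
                   max_n_rate = d$max_n_rate)
  }) |>
    purrr::list_rbind()

  decide <- function(df, max_rate) {
    if (nrow(df) < 4 || length(unique(df$x)) < 3) {
      return(dplyr::mutate(screen_and_select(NULL, NULL, max_rate),
                           flag = "insufficient_data", n_obs = nrow(df)))
    }
    dplyr::mutate(fit_and_select(df$x, df$y, max_rate, r2_threshold),
                  flag = NA_character_, n_obs = nrow(df))
  }

  vi_data <- zonal |>
    dplyr::filter(.data$timing %in% .env$timings, .data$vi_name %in% .env$vis) |>
    dplyr::inner_join(roster, by = c("trial_id", "transect_id"))
  vi_dec <- vi_data |>
    dplyr::rename(x = "n_rate", y = "mean_value") |>
    tidyr::nest(.by = c("trial_id", "transect_id", "timing", "vi_name",
                        "max_n_rate")) |>
    dplyr::mutate(dec = purrr::map2(.data$data, .data$max_n_rate, decide)) |>
    dplyr::select(-"data") |>
    tidyr::unnest("dec")

  vi_grid <- roster |>
    tidyr::expand_grid(timing = timings, vi_name = vis) |>
    dplyr::select(-"max_n_rate")
  vi_dec <- vi_grid |>
    dplyr::left_join(vi_dec, by = c("trial_id", "transect_id", "timing", "vi_name")) |>
    dplyr::mutate(flag = dplyr::if_else(is.na(.data$selected) & is.na(.data$lp_verdict),
                                        "missing_data", .data$flag))

  y_dec <- yields |>
    dplyr::inner_join(roster, by = c("trial_id", "transect_id")) |>
    dplyr::rename(x = "n_rate", y = "yield") |>
    tidyr::nest(.by = c("trial_id", "transect_id", "max_n_rate")) |>
    dplyr::mutate(dec = purrr::map2(.data$data, .data$max_n_rate, decide)) |>
    dplyr::select(-"data") |>
    tidyr::unnest("dec") |>
    dplyr::mutate(timing = NA_integer_, vi_name = "yield")

  dplyr::bind_rows(vi_dec, y_dec) |>
    dplyr::mutate(
      vi_group = dplyr::if_else(
        .data$vi_name == "yield", "yield",
        vi_definitions()$group[match(.data$vi_name, vi_definitions()$vi_name)]
      )
    ) |>
    dplyr::relocate("vi_group", .after = "vi_name")
}

#' Retention summary of screened response curves
#'
#' Percentage of VI-N curves (yield rows excluded) that survived
#' screening and carry an AONR, within each group defined by `by`.
#'
#' @param decisions Tibble from [run_curve_battery()].
#' @param by Character vector of grouping columns (empty for overall).
#' @return Tibble with `n_curves`, `n_usable`, `pct_usable` per group.
#' @export
retention_summary <- function(decisions, by = character()) {
  decisions |>
    dplyr::filter(.data$vi_name != "yield") |>
    dplyr::summarise(
      n_curves = dplyr::n(),
      n_usable = sum(!is.na(.data$aonr)),
      pct_usable = 100 * .data$n_usable / .data$n_curves,
      .by = dplyr::all_of(by)
    )
}
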