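#' Simple linear regression of yield on one vegetation index
#'
#' Ordinary least squares of `y` (grain yield) on `x` (subplot-mean VI),
#' with the coefficient of determination `1 - RSS/TSS`, the RMSE of the
#' fitted values (`sqrt(mean(residual^2))`), the normalized RMSE (RMSE
#' divided by the range of observed yields), and a two-sided t-test on
#' the slope. Models with `p < 0.10` are marked significant.
#'
#' Degenerate inputs (fewer than 3 observations, constant `x`) return a
#' flagged row with `NA` statistics so battery enumerations stay
#' complete.
#'
#' @param x Numeric vector of VI means (one value per subplot).
#' @param y Numeric vector of yields (Mg/ha), same length.
#' @param p_threshold Significance threshold on the slope p-value.
#' @return One-row tibble: `n_obs`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `rmse`, `nrmse`, `significant`, `flag`.
#' @export
#' @examples
#' fit_vi_yield(c(1, 2, 3), c(1, 2, 2)) # slope 0.5, R^2 0.75
fit_vi_yield <- function(x, y, p_threshold = 0.10) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  empty <- tibble::tibble(
    n_obs = n, slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
    p_value = NA_real_, rmse = NA_real_, nrmse = NA_real_, significant = NA,
    flag = NA_character_
  )
  if (n < 3) { empty$flag <- "too_few_obs"; return(empty) }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) { empty$flag <- "constant_vi"; return(empty) }

  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  rmse <- sqrt(rss / n)
  yrange <- max(y) - min(y)
  nrmse <- if (yrange > 0) rmse / yrange else NA_real_
  se_slope <- sqrt(rss / (n - 2) / sxx)
  p <- if (se_slope > 0) 2 * pt(-abs(slope / se_slope), df = n - 2) else 0

  tibble::tibble(
    n_obs = n, slope = slope, intercept = intercept, r_squared = r2,
    p_value = p, rmse = rmse, nrmse = nrmse,
    significant = p < p_threshold, flag = NA_character_
  )
}

#' Fit the full field x timing x VI regression battery
#'
#' One yield-on-VI regression per (trial, timing, VI) combination.
#' Combinations absent from the data are emitted as flagged placeholder
#' rows, so the battery always enumerates `trials x timings x VIs`.
#'
#' @param zonal Long zonal table (from [zonal_vi_table()] rows bound
#'   across scenes/trials): `trial_id`, `subplot_id`, `timing`,
#'   `vi_name`, `mean_value`.
#' @param yields Tibble of cleaned subplot yields: `trial_id`,
#'   `subplot_id`, `yield`.
#' @param timing_calendar Tibble mapping `timing` to `period`
#'   (default [default_timing_calendar()]).
#' @param vis Vegetation indices to enumerate (default all sixteen).
#' @param timings Timings to enumerate (default: those in the calendar).
#' @param p_threshold Significance threshold (default 0.10).
#' @return Tibble with one row per combination: keys (`trial_id`,
#'   `timing`, `period`, `vi_name`, `vi_group`) plus the columns of
#'   [fit_vi_yield()].
#' @export
run_regression_battery <- function(zonal, yields,
                                   timing_calendar = default_timing_calendar(),
                                   vis = vi_names(),
                                   timings = timing_calendar$timing,
                                   p_threshold = 0.10) {
  if (!all(timings %in% timing_calendar$timing)) {
    stop("requested timing missing from the timing calendar")
  }
  data <- zonal |>
    dplyr::filter(.data$timing %in% .env$timings, .data$vi_name %in% .env$vis) |>
    dplyr::inner_join(yields, by = c("trial_id", "subplot_id"))

  fitted <- data |>
    dplyr::reframe(fit_vi_yield(.data$mean_value, .data$yield, p_threshold),
                   .by = c("trial_id", "timing", "vi_name"))

  grid <- tidyr::expand_grid(
    trial_id = unique(zonal$trial_id), timing = timings, vi_name = vis
  )
  grid |>
    dplyr::left_join(fitted, by = c("trial_id", "timing", "vi_name")) |>
    dplyr::mutate(
      n_obs = dplyr::coalesce(.data$n_obs, 0L),
      flag = dplyr::if_else(is.na(.data$flag) & .data$n_obs == 0,
                            "missing_data", .data$flag),
      vi_group = vi_definitions()$group[match(.data$vi_name,
                                              vi_definitions()$vi_name)],
      period = timing_calendar$period[match(.data$timing,
                                            timing_calendar$timing)]
    ) |>
    dplyr::relocate("period", .after = "timing") |>
    dplyr::relocate("vi_group", .after = "vi_name")
}

#' Summarize a regression battery by period, VI group, and field
#'
#' For every combination of period, VI group (including `"ALL"`), and
#' field (including `"ALL"`): the number of models evaluated, the
#' number significant (`p < 0.10`), and the min/max R-squared and nRMSE
#' over the significant models only.
#'
#' @param results Battery tibble from [run_regression_battery()].
#' @return Summary tibble with columns `period`, `vi_group`, `trial_id`,
#'   `models`, `significant_models`, `min_r2`, `max_r2`, `min_nrmse`,
#'   `max_nrmse`.
#' @export
summarize_battery <- function(results) {
  widen <- function(df, col) {
    dplyr::bind_rows(df, dplyr::mutate(df, "{col}" := "ALL"))
  }
  rng <- function(v, f) if (any(!is.na(v))) f(v, na.rm = TRUE) else NA_real_

  results |>
    widen("vi_group") |>
    widen("trial_id") |>
    dplyr::summarise(
      models = dplyr::n(),
      significant_models = sum(.data$significant, na.rm = TRUE),
      min_r2 = rng(.data$r_squared[which(.data$significant)], min),
      max_r2 = rng(.data$r_squared[which(.data$significant)], max),
      min_nrmse = rng(.data$nrmse[which(.data$significant)], min),
      max_nrmse = rng(.data$nrmse[which(.data$significant)], max),
      .by = c("period", "vi_group", "trial_id")
    ) |>
    dplyr::arrange(dplyr::desc(.data$period), .data$vi_group, .data$trial_id)
}
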