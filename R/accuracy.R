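#' Signed percent difference between VI-based and yield-based AONR
#'
#' `(aonr_vi - aonr_y) / aonr_y * 100`; negative values mean the
#' VI-based estimate underestimates the yield-based optimum.
#'
#' @param aonr_vi,aonr_y AONR estimates (kg/ha); `aonr_y` must be
#'   positive.
#' @return Percent difference (vectorized).
#' @export
#' @examples
#' percent_difference(180, 200) # -10
percent_difference <- function(aonr_vi, aonr_y) {
  if (any(aonr_y <= 0, na.rm = TRUE)) stop("aonr_y must be positive")
  (aonr_vi - aonr_y) / aonr_y * 100
}

#' Pair retained VI-based AONRs with their transect's yield-based AONR
#'
#' One pair per retained VI-N curve (a transect can contribute one pair
#' per VI and timing), joined to the same transect's yield-N AONR.
#' Pairs exist only where both estimates survived screening.
#'
#' @param decisions Tibble from [run_curve_battery()] containing both VI
#'   and yield rows.
#' @return Tibble of pairs: keys, `aonr_vi`, `aonr_y`, `pct_diff`.
#' @export
aonr_pairs <- function(decisions) {
  yield_aonr <- decisions |>
    dplyr::filter(.data$vi_name == "yield", !is.na(.data$aonr)) |>
    dplyr::select("trial_id", "transect_id", aonr_y = "aonr")
  decisions |>
    dplyr::filter(.data$vi_name != "yield", !is.na(.data$aonr)) |>
    dplyr::select("trial_id", "transect_id", "timing", "vi_name", "vi_group",
                  aonr_vi = "aonr") |>
    dplyr::inner_join(yield_aonr, by = c("trial_id", "transect_id")) |>
    dplyr::mutate(pct_diff = percent_difference(.data$aonr_vi, .data$aonr_y))
}

#' Agreement statistics between paired AONR estimates
#'
#' Per group: the number of pairs, the mean signed percent difference,
#' the squared Pearson correlation between `aonr_y` and `aonr_vi`
#' (reported as `NA` when a group has fewer than two pairs or either
#' variable is constant), the RMSE, and the MAE (both kg/ha, treating
#' `aonr_y` as observed).
#'
#' @param pairs Tibble from [aonr_pairs()].
#' @param by Character vector of grouping columns (empty for overall).
#' @return Tibble: group keys, `n_pairs`, `mean_pct_diff`, `r_squared`,
#'   `rmse`, `mae`.
#' @export
agreement_stats <- function(pairs, by = character()) {
  pearson_r2 <- function(x, y) {
    n <- length(x)
    if (n < 2) return(NA_real_)
    sx <- n * sum(x^2) - sum(x)^2
    sy <- n * sum(y^2) - sum(y)^2
    if (sx <= 0 || sy <= 0) return(NA_real_)
    r <- (n * sum(x * y) - sum(x) * sum(y)) / sqrt(sx * sy)
    r^2
  }
  pairs |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_pct_diff = mean(.data$pct_diff),
      r_squared = pearson_r2(.data$aonr_y, .data$aonr_vi),
      rmse = sqrt(mean((.data$aonr_vi - .data$aonr_y)^2)),
      mae = mean(abs(.data$aonr_vi - .data$aonr_y)),
      .by = dplyr::all_of(by)
    )
}
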