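#' Heatmap of VI-yield regression strength
#'
#' Tiles of R-squared by vegetation index and timing, faceted by trial;
#' non-significant models are shown in grey.
#'
#' @param results Battery tibble from [run_regression_battery()].
#' @return A ggplot object.
#' @export
plot_r2_heatmap <- function(results) {
  df <- results |>
    dplyr::mutate(
      r2_shown = dplyr::if_else(.data$significant %in% TRUE,
                                .data$r_squared, NA_real_)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$timing), y = .data$vi_name,
                                   fill = .data$r2_shown)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_grid(ggplot2::vars(.data$vi_group),
                        ggplot2::vars(.data$trial_id),
                        scales = "free_y") +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = expression(R^2)) +
    ggplot2::labs(x = "image timing", y = NULL,
                  title = "VI-yield regression strength (grey: p >= 0.10)") +
    ggplot2::theme_minimal()
}

#' Heatmap of response-curve retention
#'
#' Percentage of VI-N curves surviving the screening criteria, by
#' vegetation index and timing.
#'
#' @param decisions Tibble from [run_curve_battery()].
#' @return A ggplot object.
#' @export
plot_retention <- function(decisions) {
  df <- retention_summary(decisions, c("vi_group", "vi_name", "timing"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$timing), y = .data$vi_name,
                                   fill = .data$pct_usable)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$pct_usable)),
                       size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$vi_group), scales = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "% usable") +
    ggplot2::labs(x = "image timing", y = NULL,
                  title = "VI-N curves retained after screening") +
    ggplot2::theme_minimal()
}

#' Scatter of yield-based vs VI-based AONR
#'
#' Retained pairs against the 1:1 line, faceted by trial.
#'
#' @param pairs Tibble from [aonr_pairs()].
#' @return A ggplot object.
#' @export
plot_aonr_agreement <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$aonr_y, y = .data$aonr_vi,
                                      colour = .data$vi_group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trial_id)) +
    ggplot2::labs(x = "AONRy (kg/ha)", y = "AONRvi (kg/ha)",
                  title = "VI-based vs yield-based optimum N rate") +
    ggplot2::theme_minimal()
}
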