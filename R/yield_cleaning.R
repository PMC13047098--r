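#' Default yield-monitor cleaning thresholds
#'
#' Grain moisture outside 10-33%, travel speed outside 0.7-8.2 mph,
#' speed changes above 15% of the previous reading, headings more than
#' 30 degrees from the pass's circular median, and per-treatment yields
#' beyond 3 standard deviations of the treatment mean are removed.
#' Yields are standardized to 15% moisture (150 g/kg).
#'
#' @return Named list of thresholds.
#' @export
clean_thresholds <- function() {
  list(
    moisture_min = 10, moisture_max = 33,
    speed_min = 0.7, speed_max = 8.2,
    speed_jump = 0.15,
    heading_max_dev = 30,
    outlier_k = 3,
    standard_moisture = 0.15
  )
}

# Circular median of headings in degrees: the observed heading
# minimizing total wrapped angular distance.
circular_median_deg <- function(deg) {
  cand <- unique(deg)
  wrap <- function(d) abs((d + 180) %% 360 - 180)
  tot <- vapply(cand, function(m) sum(wrap(deg - m)), numeric(1))
  cand[which.min(tot)]
}

#' Flag yield-monitor points against the cleaning rules
#'
#' Applies, in order: outside-area (the point lies in no subplot
#' rectangle), abnormal heading (more than `heading_max_dev` degrees
#' from the pass's circular median), moisture range, speed range, and
#' speed jump (relative change from the immediately preceding recorded
#' point in the same pass above `speed_jump`). All applicable flags are
#' recorded; a point is retained when it has none.
#'
#' The speed-jump and heading references (`prev_speed`,
#' `pass_heading_ref`) are computed from the original sequence and kept
#' as columns, so re-filtering an already-filtered table flags nothing
#' new.
#'
#' @param points Tibble with columns `pass_id`, `seq`, `x`, `y`,
#'   `heading_deg`, `speed_mph`, `moisture_pct`, `wet_yield`, ordered by
#'   acquisition sequence within each pass.
#' @param zones Tibble of subplot rectangles (`subplot_id`, `transect_id`,
#'   `treatment`, `n_rate`, `xmin`, `xmax`, `ymin`, `ymax`), e.g.
#'   `design$subplot_rects`.
#' @param thresholds See [clean_thresholds()].
#' @return The points tibble with assigned `subplot_id`/`treatment`/
#'   `n_rate`, reference columns, a `flags` character column
#'   (comma-separated reasons, `""` if clean) and logical `retained`.
#' @export
filter_points <- function(points, zones, thresholds = clean_thresholds()) {
  req <- c("pass_id", "x", "y", "heading_deg", "speed_mph", "moisture_pct", "wet_yield")
  miss <- setdiff(req, names(points))
  if (length(miss) > 0) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"seq" %in% names(points)) {
    points <- points |> dplyr::mutate(seq = dplyr::row_number(), .by = "pass_id")
  }
  if (any(unlist(tapply(points$seq, points$pass_id, is.unsorted)))) {
    stop("points must be ordered by acquisition sequence within each pass")
  }

  # zone assignment by half-open rectangle containment
  sub <- rep(NA_character_, nrow(points))
  trt <- rep(NA_character_, nrow(points))
  nra <- rep(NA_real_, nrow(points))
  tra <- rep(NA_character_, nrow(points))
  for (j in seq_len(nrow(zones))) {
    inside <- points$x >= zones$xmin[j] & points$x < zones$xmax[j] &
      points$y >= zones$ymin[j] & points$y < zones$ymax[j]
    sub[inside] <- zones$subplot_id[j]
    trt[inside] <- zones$treatment[j]
    nra[inside] <- zones$n_rate[j]
    tra[inside] <- zones$transect_id[j]
  }
  points$subplot_id <- sub
  points$treatment <- trt
  points$n_rate <- nra
  points$transect_id <- tra

  if (!"prev_speed" %in% names(points)) {
    points <- points |>
      dplyr::mutate(prev_speed = dplyr::lag(.data$speed_mph), .by = "pass_id")
  }
  if (!"pass_heading_ref" %in% names(points)) {
    points <- points |>
      dplyr::mutate(pass_heading_ref = circular_median_deg(.data$heading_deg),
                    .by = "pass_id")
  }

  th <- thresholds
  hdev <- abs((points$heading_deg - points$pass_heading_ref + 180) %% 360 - 180)
  f_outside <- is.na(points$subplot_id)
  f_heading <- hdev > th$heading_max_dev
  f_moist <- points$moisture_pct < th$moisture_min | points$moisture_pct > th$moisture_max
  f_speed <- points$speed_mph < th$speed_min | points$speed_mph > th$speed_max
  f_jump <- !is.na(points$prev_speed) &
    abs(points$speed_mph - points$prev_speed) / points$prev_speed > th$speed_jump

  reasons <- cbind(outside_area = f_outside, heading = f_heading,
                   moisture_range = f_moist, speed_range = f_speed,
                   speed_jump = f_jump)
  points$flags <- apply(reasons, 1, function(r) {
    paste(colnames(reasons)[r], collapse = ",")
  })
  points$retained <- points$flags == ""
  points
}

#' Standardize wet yield to 15% grain moisture
#'
#' `adjusted = wet_yield * (1 - moisture/100) / (1 - 0.15)`: the dry
#' matter in the harvested grain re-expressed at the standard 150 g/kg
#' water content.
#'
#' @param wet_yield Wet yield (Mg/ha).
#' @param moisture_pct Grain moisture, percent wet basis, in `[0, 100)`.
#' @param standard Standard moisture as a fraction (default 0.15).
#' @return Adjusted yield (Mg/ha) at standard moisture.
#' @export
#' @examples
#' standardize_moisture(10, 20) # 10 * 0.80 / 0.85
standardize_moisture <- function(wet_yield, moisture_pct, standard = 0.15) {
  if (any(moisture_pct < 0 | moisture_pct >= 100, na.rm = TRUE)) {
    stop("moisture must lie in [0, 100)")
  }
  wet_yield * (1 - moisture_pct / 100) / (1 - standard)
}

#' Flag extreme yields beyond k standard deviations of the group mean
#'
#' Single pass: the mean and sd are computed on each group before any
#' removal, and values with `|y - mean| > k * sd` are flagged. Groups of
#' fewer than two points pass through with a warning.
#'
#' @param data Tibble of observations.
#' @param value Column (tidy-eval) holding the values to screen.
#' @param by Character vector of grouping columns (e.g. `"treatment"`).
#' @param k Multiplier on the standard deviation (default 3).
#' @return `data` with a logical `outlier` column.
#' @export
remove_treatment_outliers <- function(data, value, by = "treatment", k = 3) {
  val <- rlang::enquo(value)
  out <- data |>
    dplyr::mutate(
      .n = dplyr::n(),
      .mu = mean(!!val),
      .sd = sd(!!val),
      outlier = .data$.n >= 2 & abs(!!val - .data$.mu) > k * .data$.sd,
      .by = dplyr::all_of(by)
    )
  n_small <- sum(out$.n < 2)
  if (n_small > 0) {
    warning(sprintf("%d group(s) with fewer than 2 points passed through unscreened",
                    n_small))
  }
  dplyr::select(out, -".n", -".mu", -".sd")
}

#' Clean a yield-monitor point stream end to end
#'
#' Runs [filter_points()], standardizes retained yields to 15% moisture,
#' then flags per-treatment outliers beyond `k` standard deviations on
#' the adjusted yields (in that order). Returns the audited point table,
#' per-subplot mean yields, and an audit report of counts per removal
#' reason.
#'
#' @inheritParams filter_points
#' @param outlier_by `"treatment_within_field"` (default) or
#'   `"treatment_within_transect"`: the grouping for the outlier screen.
#' @return List with `points` (all input points with `flags`,
#'   `adjusted_yield` -- `NA` unless the point survived every screen --
#'   and `retained`), `subplot_yield` (tibble of per-subplot mean
#'   adjusted yield and point count), and `audit` (list of counts per
#'   reason and the thresholds used).
#' @export
clean_yield <- function(points, zones, thresholds = clean_thresholds(),
                        outlier_by = c("treatment_within_field",
                                       "treatment_within_transect")) {
  outlier_by <- match.arg(outlier_by)
  n_input <- nrow(points)
  pts <- filter_points(points, zones, thresholds)

  pts$adjusted_yield <- NA_real_
  keep <- pts$retained
  pts$adjusted_yield[keep] <- standardize_moisture(
    pts$wet_yield[keep], pts$moisture_pct[keep], thresholds$standard_moisture
  )

  grp <- if (outlier_by == "treatment_within_field") "treatment"
         else c("transect_id", "treatment")
  screened <- pts[keep, ] |>
    remove_treatment_outliers(.data$adjusted_yield, by = grp,
                              k = thresholds$outlier_k)
  out_ids <- which(keep)[screened$outlier]
  if (length(out_ids) > 0) {
    pts$flags[out_ids] <- "treatment_outlier"
    pts$retained[out_ids] <- FALSE
    pts$adjusted_yield[out_ids] <- NA_real_
  }

  reason_levels <- c("outside_area", "heading", "moisture_range",
                     "speed_range", "speed_jump", "treatment_outlier")
  counts <- vapply(reason_levels, function(r) {
    sum(vapply(strsplit(pts$flags, ","), function(f) r %in% f, logical(1)))
  }, numeric(1))

  subplot_yield <- pts |>
    dplyr::filter(.data$retained) |>
    dplyr::summarise(
      yield = mean(.data$adjusted_yield),
      n_points = dplyr::n(),
      .by = dplyr::any_of(c("trial_id", "transect_id", "subplot_id",
                            "treatment", "n_rate"))
    )

  list(
    points = pts,
    subplot_yield = subplot_yield,
    audit = list(
      n_input = n_input,
      n_retained = sum(pts$retained),
      n_flagged = sum(!pts$retained),
      counts_by_reason = as.list(counts),
      thresholds = thresholds,
      outlier_by = outlier_by
    )
  )
}
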