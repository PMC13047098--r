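#' Vegetation index definitions
#'
#' The sixteen vegetation indices used throughout the package: eight
#' RGB-based (visible bands only) and eight NIR-based. Formulas are
#' expressed on reflectance in `[0, 1]` (after [rescale_reflectance()]).
#'
#' Two naming caveats inherited from the source index tables:
#' * `DVI` here is the *Green-Red Difference* Vegetation Index, `G - R`,
#'   not the usual NIR-based difference index.
#' * `GARI` is the standard normalized ratio `(NIR - X)/(NIR + X)` with
#'   `X = G - 1.7 (B - R)`.
#' `GREEN` is the green band itself (identity index).
#'
#' @return A tibble with columns `vi_name`, `group` (`"RGB"` or `"NIR"`),
#'   `full_name`, and `formula` (a human-readable band expression).
#' @export
#' @examples
#' vi_definitions()
vi_definitions <- function() {
  tibble::tribble(
    ~vi_name, ~group, ~full_name, ~formula,
    "EXG",   "RGB", "Excess Greenness Index",                       "2G - R - B",
    "EXR",   "RGB", "Excess Red Index",                             "1.4R - B",
    "VDVI",  "RGB", "Visible-band Difference Vegetation Index",     "(2G - B - R)/(2G + B + R)",
    "PPRB",  "RGB", "Plant Pigment Ratio",                          "(G - B)/(G + B)",
    "VARI",  "RGB", "Visible Atmospherically Resistant Index",      "(G - R)/(G + R - B)",
    "VIG",   "RGB", "Vegetation Index Green",                       "(G - R)/(G + R)",
    "DVI",   "RGB", "Green-Red Difference Vegetation Index",        "G - R",
    "GREEN", "RGB", "Green spectral band",                          "G",
    "NDVI",  "NIR", "Normalized Difference Vegetation Index",       "(NIR - R)/(NIR + R)",
    "GNDVI", "NIR", "Green Normalized Difference Vegetation Index", "(NIR - G)/(NIR + G)",
    "OSAVI", "NIR", "Optimized Soil-Adjusted Vegetation Index",     "(NIR - R)/(NIR + R + 0.16)",
    "SAVI",  "NIR", "Soil-Adjusted Vegetation Index",               "1.5 (NIR - R)/(NIR + R + 0.5)",
    "CVI",   "NIR", "Chlorophyll Vegetation Index",                 "(NIR/G) (R/G)",
    "RDVI",  "NIR", "Renormalized Difference Vegetation Index",     "(NIR - R)/sqrt(NIR + R)",
    "GARI",  "NIR", "Green Atmospherically Resistant Index",        "(NIR - X)/(NIR + X), X = G - 1.7(B - R)",
    "EVI2",  "NIR", "Two-Band Enhanced Vegetation Index",           "2.5 (NIR - R)/(NIR + 2.4R + 1)"
  )
}

#' Names of all sixteen vegetation indices
#' @param group Optionally restrict to `"RGB"` or `"NIR"`.
#' @return Character vector of index names.
#' @export
vi_names <- function(group = NULL) {
  def <- vi_definitions()
  if (!is.null(group)) def <- def[def$group == group, ]
  def$vi_name
}

#' Rescale scaled-integer reflectance to the unit interval
#'
#' Surface-reflectance rasters store reflectance as integers in
#' `0..10000` (reflectance times 10,000). This divides by 10,000; values
#' above 10,000 are clipped to 1 with a warning reporting how many.
#'
#' @param x Numeric vector, matrix, or array of scaled-integer values.
#' @return Object of the same shape with values in `[0, 1]`.
#' @export
#' @examples
#' rescale_reflectance(c(0, 5000, 10000))
rescale_reflectance <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("negative reflectance values are not valid scaled-integer input")
  }
  n_over <- sum(x > 10000, na.rm = TRUE)
  if (n_over > 0) {
    warning(sprintf("%d value(s) exceeded 10000; clipped to 1.0", n_over))
    x[!is.na(x) & x > 10000] <- 10000
  }
  x / 10000
}

# Evaluate one index on reflectance band matrices/vectors; zero
# denominators become NA (kept out of zonal means downstream).
vi_evaluate <- function(vi_name, B, G, R, NIR) {
  safe_div <- function(num, den) {
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  switch(vi_name,
    EXG   = 2 * G - R - B,
    EXR   = 1.4 * R - B,
    VDVI  = safe_div(2 * G - B - R, 2 * G + B + R),
    PPRB  = safe_div(G - B, G + B),
    VARI  = safe_div(G - R, G + R - B),
    VIG   = safe_div(G - R, G + R),
    DVI   = G - R,
    GREEN = G,
    NDVI  = safe_div(NIR - R, NIR + R),
    GNDVI = safe_div(NIR - G, NIR + G),
    OSAVI = safe_div(NIR - R, NIR + R + 0.16),
    SAVI  = 1.5 * safe_div(NIR - R, NIR + R + 0.5),
    CVI   = safe_div(NIR, G) * safe_div(R, G),
    RDVI  = safe_div(NIR - R, sqrt(NIR + R)),
    GARI  = {
      X <- G - 1.7 * (B - R)
      safe_div(NIR - X, NIR + X)
    },
    EVI2  = safe_div(2.5 * (NIR - R), NIR + 2.4 * R + 1),
    stop(sprintf("unknown vegetation index '%s'", vi_name))
  )
}

#' Compute a vegetation index grid from a rescaled scene
#'
#' Element-wise evaluation of one of the sixteen index formulas over a
#' scene's band grids. Pixels with a zero denominator are set to `NA`.
#'
#' @param scene A [spectral_scene], already rescaled to reflectance in
#'   `[0, 1]` (see [rescale_scene()]).
#' @param vi Index name; one of [vi_names()].
#' @return A numeric matrix the shape of the scene's bands.
#' @export
compute_vi <- function(scene, vi) {
  stopifnot(inherits(scene, "spectral_scene"))
  if (!isTRUE(scene$rescaled)) {
    stop("scene holds scaled integers; call rescale_scene() before compute_vi()")
  }
  if (!vi %in% vi_definitions()$vi_name) {
    stop(sprintf("unknown vegetation index '%s'", vi))
  }
  b <- scene$bands
  vi_evaluate(vi, b$B, b$G, b$R, b$NIR)
}

#' Zonal means of an index grid over subplot zones
#'
#' Averages grid values over the pixels of each zone (subplot), skipping
#' `NA` pixels. Zones whose pixels are all `NA` are dropped (with a
#' message); `pixel_count` reports the pixels actually averaged.
#'
#' @param grid Numeric matrix (e.g. from [compute_vi()]).
#' @param zones Tibble with one row per pixel: columns `row`, `col`,
#'   `subplot_id` and any subplot-level keys (`trial_id`, `transect_id`,
#'   `treatment`, `n_rate`) which are carried through.
#' @return Tibble with one row per zone: the key columns plus
#'   `mean_value` and `pixel_count`.
#' @export
zonal_means <- function(grid, zones) {
  if (nrow(zones) == 0) stop("empty zone table")
  stopifnot(all(c("row", "col", "subplot_id") %in% names(zones)))
  if (any(zones$row < 1 | zones$row > nrow(grid) |
            zones$col < 1 | zones$col > ncol(grid))) {
    stop("zone table references pixels outside the grid")
  }
  vals <- grid[cbind(zones$row, zones$col)]
  key_cols <- setdiff(names(zones), c("row", "col"))
  out <- zones |>
    dplyr::mutate(.val = vals) |>
    dplyr::summarise(
      mean_value = mean(.data$.val, na.rm = TRUE),
      pixel_count = sum(!is.na(.data$.val)),
      .by = dplyr::all_of(key_cols)
    )
  n_empty <- sum(out$pixel_count == 0)
  if (n_empty > 0) {
    message(sprintf("%d zone(s) had no valid pixels and were dropped", n_empty))
    out <- out[out$pixel_count > 0, ]
  }
  out$mean_value[is.nan(out$mean_value)] <- NA_real_
  out
}

#' Zonal table of all requested indices for one scene
#'
#' Convenience wrapper: rescales if needed, computes each index, and
#' stacks the zonal means into one long table with `timing` attached.
#'
#' @inheritParams compute_vi
#' @inheritParams zonal_means
#' @param vis Character vector of index names (default all sixteen).
#' @return Long tibble: zone keys, `timing`, `vi_name`, `mean_value`,
#'   `pixel_count`.
#' @export
zonal_vi_table <- function(scene, zones, vis = vi_names()) {
  if (!isTRUE(scene$rescaled)) scene <- rescale_scene(scene)
  purrr::map(vis, function(v) {
    zonal_means(compute_vi(scene, v), zones) |>
      dplyr::mutate(timing = scene$timing, vi_name = v)
  }) |>
    purrr::list_rbind()
}
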