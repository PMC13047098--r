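#' Default timing calendar
#'
#' Seven image timings spanning mid-vegetative to maturity. Timings 1-3
#' (V7-V16) are the vegetative window used for N-response curves; 4-7
#' (R1-R6) are reproductive.
#'
#' @return Tibble with columns `timing`, `stage`, `period`.
#' @export
default_timing_calendar <- function() {
  tibble::tibble(
    timing = 1:7,
    stage = c("V7-V8", "V10-V11", "V15-V16", "R1-R2", "R3-R4", "R5", "R6"),
    period = c(rep("vegetative", 3), rep("reproductive", 4))
  )
}

#' Default spectral endmembers (synthetic)
#'
#' Per-material reflectance for the four bands used by the linear
#' mixing model. These are plausible synthetic values for green corn
#' canopy, bare agricultural soil, and dry crop residue -- not
#' measurements from any instrument.
#'
#' @return Tibble with columns `material`, `B`, `G`, `R`, `NIR`.
#' @export
default_endmembers <- function() {
  tibble::tribble(
    ~material, ~B,   ~G,   ~R,   ~NIR,
    "canopy",  0.03, 0.08, 0.05, 0.50,
    "soil",    0.07, 0.10, 0.14, 0.22,
    "residue", 0.16, 0.22, 0.27, 0.36
  )
}

#' Default trial roster
#'
#' Three trials mirroring a strip-till soybean-corn field (ST-S) and two
#' conventionally tilled fields (CT-C, CT-S), with treatments expressed
#' as percentages of each farmer's normal rate (FNR). The CT trials
#' duplicate the 50%FNR treatment, so every trial has five subplots per
#' transect. `residue_fraction` sets the residue share of the background
#' (non-canopy) signal in rendered scenes.
#'
#' @return List of per-trial specs (`trial_id`, `fnr`, `treatments`
#'   tibble, `residue_fraction`, `true_aonr_mean`, `true_aonr_sd`).
#' @export
default_trials <- function() {
  list(
    list(
      trial_id = "ST-S", fnr = 222, residue_fraction = 0.70,
      treatments = tibble::tibble(
        treatment = c("20%FNR", "40%FNR", "70%FNR", "100%FNR", "130%FNR"),
        n_rate = c(44, 89, 155, 222, 289)
      ),
      true_aonr_mean = 0.8 * 222, true_aonr_sd = 25
    ),
    list(
      trial_id = "CT-C", fnr = 222, residue_fraction = 0.30,
      treatments = tibble::tibble(
        treatment = c("50%FNR#1", "50%FNR#2", "70%FNR", "100%FNR", "130%FNR"),
        n_rate = c(111, 111, 155, 222, 289)
      ),
      true_aonr_mean = 0.8 * 222, true_aonr_sd = 25
    ),
    list(
      trial_id = "CT-S", fnr = 180, residue_fraction = 0.10,
      treatments = tibble::tibble(
        treatment = c("50%FNR#1", "50%FNR#2", "70%FNR", "100%FNR", "130%FNR"),
        n_rate = c(90, 90, 126, 180, 234)
      ),
      true_aonr_mean = 0.8 * 180, true_aonr_sd = 20
    )
  )
}

#' Simulation configuration for virtual field trials
#'
#' Bundles the trial roster, geometry, timing calendar, spectral
#' endmembers, response-model parameters, and noise levels that drive
#' the synthetic generator. Defaults emulate a three-trial on-farm strip
#' study: 8 transects per trial, 5 N-rate subplots per transect, 3-m
#' pixels, 1.5-m buffers between adjacent subplots and 15-m buffers
#' between consecutive subplots, and seven image timings.
#'
#' @param trials List of trial specs; see [default_trials()].
#' @param transects_per_trial Transects (replicate N-rate strips) per trial.
#' @param subplot_length_m,plot_width_m Subplot dimensions in meters.
#' @param buffer_adjacent_m,buffer_consecutive_m Buffer widths in meters.
#' @param pixel_size_m Scene pixel size in meters.
#' @param timings Timing calendar tibble; see [default_timing_calendar()].
#' @param endmembers Endmember tibble; see [default_endmembers()].
#' @param yield_model Plateau family and yield parameters (Mg/ha):
#'   `family` (`"quadratic_plateau"` or `"linear_plateau"`),
#'   `yield_at_zero_n`, `plateau_yield`, and between-transect sds
#'   `zero_n_sd`, `plateau_sd`.
#' @param canopy Canopy-fraction model: logistic growth over timing index
#'   (`k`, midpoint `t0`) scaled by N sufficiency `min(1, N/AONR)^gamma`.
#' @param noise_sd_reflectance Per-band reflectance noise sd (unitless).
#' @param noise_sd_yield Yield-point noise sd (Mg/ha, dry-adjusted basis).
#' @param yield_points_per_subplot Target yield-monitor points per subplot.
#' @param passes_per_subplot Harvest passes across each subplot's width.
#' @param artifact_fraction Fraction of in-subplot points given injected
#'   monitor artifacts (hidden truth labels are kept for recall tests).
#' @param seed Integer master seed; all streams derive from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(trials = default_trials(),
                       transects_per_trial = 8,
                       subplot_length_m = 55,
                       plot_width_m = 18.29,
                       buffer_adjacent_m = 1.5,
                       buffer_consecutive_m = 15,
                       pixel_size_m = 3,
                       timings = default_timing_calendar(),
                       endmembers = default_endmembers(),
                       yield_model = list(family = "quadratic_plateau",
                                          yield_at_zero_n = 7.5, plateau_yield = 13,
                                          zero_n_sd = 0.5, plateau_sd = 0.6),
                       canopy = list(k = 1.2, t0 = 2.5, gamma = 0.5),
                       noise_sd_reflectance = 0.01,
                       noise_sd_yield = 0.4,
                       yield_points_per_subplot = 30,
                       passes_per_subplot = 2,
                       artifact_fraction = 0.05,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$trials) >= 1,
    cfg$transects_per_trial >= 1,
    cfg$buffer_adjacent_m >= 0, cfg$buffer_consecutive_m >= 0
  )
  if (cfg$subplot_length_m <= 0 || cfg$plot_width_m <= 0 || cfg$pixel_size_m <= 0) {
    stop("subplot dimensions and pixel size must be positive")
  }
  em <- cfg$endmembers
  stopifnot(all(c("canopy", "soil", "residue") %in% em$material),
            all(c("B", "G", "R", "NIR") %in% names(em)))
  if (any(em[c("B", "G", "R", "NIR")] < 0 | em[c("B", "G", "R", "NIR")] > 1)) {
    stop("endmember reflectance must lie in [0, 1]")
  }
  for (tr in cfg$trials) {
    rates <- tr$treatments$n_rate
    if (any(rates <= 0)) stop("N rates must be strictly positive")
    if (is.unsorted(rates)) stop("N rates must be sorted increasing")
    if (length(unique(rates)) < 3) {
      stop("fewer than 3 distinct N rates: plateau models are unidentifiable")
    }
    if (tr$residue_fraction < 0 || tr$residue_fraction > 1) {
      stop("residue_fraction must lie in [0, 1]")
    }
  }
  if (cfg$artifact_fraction < 0 || cfg$artifact_fraction > 1) {
    stop("artifact_fraction must lie in [0, 1]")
  }
  invisible(cfg)
}

# Derive a stream seed from the master seed; stays below 2^31.
make_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147400000 + offset * 97003) %% 2147483629)
}

# Truncated-normal draw by rejection (bounds in (lo, hi]).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, mean, sd)
      if (v > lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Expected response of a plateau dose-response family
#'
#' The noiseless response at given N rates: rising linearly
#' (`linear_plateau`) or along a concave parabola (`quadratic_plateau`,
#' smooth vertex) from the zero-N value `y0` to `plateau`, reached at
#' `aonr` and constant beyond.
#'
#' @param n_rate N rates (kg/ha).
#' @param y0 Response at zero N.
#' @param plateau Response on the plateau.
#' @param aonr Join point (kg/ha).
#' @param family `"linear_plateau"` or `"quadratic_plateau"`.
#' @return Expected response values.
#' @export
plateau_expectation <- function(n_rate, y0, plateau, aonr, family) {
  if (family == "linear_plateau") {
    y0 + (plateau - y0) / aonr * pmin(n_rate, aonr)
  } else if (family == "quadratic_plateau") {
    cc <- (y0 - plateau) / aonr^2
    bb <- -2 * cc * aonr
    ifelse(n_rate < aonr, y0 + bb * n_rate + cc * n_rate^2, plateau)
  } else {
    stop(sprintf("unknown plateau family '%s'", family))
  }
}

canopy_fraction <- function(timing, n_rate, aonr, canopy) {
  l <- 1 / (1 + exp(-canopy$k * (timing - canopy$t0)))
  s <- pmin(1, n_rate / aonr)^canopy$gamma
  pmin(1, l * s)
}

#' Generate one virtual trial: design and ground truth
#'
#' Lays out the transect-by-treatment subplot grid with buffers, draws
#' each transect's true agronomic optimum N rate (AONR) from a truncated
#' normal, and computes per-subplot expected yields (plateau family) and
#' canopy fractions by timing. Deterministic for a given config and
#' `trial_index`.
#'
#' @param config A [sim_config()].
#' @param trial_index Index into `config$trials`.
#' @return List with elements `design` (trial layout: subplots, pixel
#'   zones, subplot rectangles, treatments, timing calendar, max N rate)
#'   and `truth` (per-transect true AONR and yield parameters,
#'   per-subplot expected yield, canopy fractions by timing).
#' @export
generate_trial <- function(config, trial_index) {
  validate_sim_config(config)
  tr <- config$trials[[trial_index]]
  n_tr <- config$transects_per_trial
  trts <- tr$treatments
  k <- nrow(trts)

  set.seed(make_seed(config$seed, 11 + trial_index))

  transect_id <- sprintf("T%02d", seq_len(n_tr))
  max_rate <- max(trts$n_rate)
  true_aonr <- rnorm_trunc(n_tr, tr$true_aonr_mean, tr$true_aonr_sd, 0, max_rate)
  ym <- config$yield_model
  y0 <- rnorm(n_tr, ym$yield_at_zero_n, ym$zero_n_sd)
  plateau <- pmax(rnorm(n_tr, ym$plateau_yield, ym$plateau_sd), y0 + 0.5)

  transects <- tibble::tibble(
    trial_id = tr$trial_id, transect_id = transect_id,
    true_aonr = true_aonr, yield_at_zero_n = y0, plateau_yield = plateau
  )

  subplots <- tidyr::expand_grid(transect_id = transect_id, trts) |>
    dplyr::mutate(
      trial_id = tr$trial_id,
      subplot_id = sprintf("%s_%s_%s", tr$trial_id, .data$transect_id, .data$treatment),
      .before = 1
    )

  subplot_truth <- subplots |>
    dplyr::left_join(transects, by = c("trial_id", "transect_id")) |>
    dplyr::mutate(
      expected_yield = plateau_expectation(
        .data$n_rate, .data$yield_at_zero_n, .data$plateau_yield,
        .data$true_aonr, ym$family
      )
    ) |>
    dplyr::select("trial_id", "transect_id", "subplot_id", "treatment",
                  "n_rate", "true_aonr", "expected_yield")

  canopy_tbl <- tidyr::expand_grid(
    subplot_truth[c("subplot_id", "n_rate", "true_aonr")],
    timing = config$timings$timing
  ) |>
    dplyr::mutate(
      canopy_fraction = canopy_fraction(.data$timing, .data$n_rate,
                                        .data$true_aonr, config$canopy)
    ) |>
    dplyr::select("subplot_id", "timing", "canopy_fraction")

  # Geometry: treatments side by side along x (1.5 m apart), transects
  # stacked along y (15 m apart); pixel centers decide zone membership.
  w <- config$plot_width_m; len <- config$subplot_length_m
  ba <- config$buffer_adjacent_m; bc <- config$buffer_consecutive_m
  px <- config$pixel_size_m
  rects <- subplots |>
    dplyr::mutate(
      col_index = match(.data$treatment, .env$trts$treatment),
      row_index = match(.data$transect_id, .env$transect_id),
      xmin = (.data$col_index - 1) * (w + ba),
      xmax = .data$xmin + w,
      ymin = (.data$row_index - 1) * (len + bc),
      ymax = .data$ymin + len
    )
  extent_x <- k * w + (k - 1) * ba
  extent_y <- n_tr * len + (n_tr - 1) * bc
  n_col <- ceiling(extent_x / px)
  n_row <- ceiling(extent_y / px)

  cx <- (seq_len(n_col) - 0.5) * px
  cy <- (seq_len(n_row) - 0.5) * px
  zones <- purrr::pmap(
    rects[c("subplot_id", "transect_id", "treatment", "n_rate",
            "xmin", "xmax", "ymin", "ymax")],
    function(subplot_id, transect_id, treatment, n_rate, xmin, xmax, ymin, ymax) {
      cols <- which(cx >= xmin & cx < xmax)
      rows <- which(cy >= ymin & cy < ymax)
      tidyr::expand_grid(row = rows, col = cols) |>
        dplyr::mutate(trial_id = tr$trial_id, transect_id = transect_id,
                      subplot_id = subplot_id, treatment = treatment,
                      n_rate = n_rate)
    }
  ) |>
    purrr::list_rbind()

  design <- structure(list(
    trial_id = tr$trial_id, trial_index = trial_index, fnr = tr$fnr,
    residue_fraction = tr$residue_fraction,
    treatments = dplyr::mutate(trts, replications = n_tr),
    transect_ids = transect_id,
    timing_calendar = config$timings,
    max_n_rate = max_rate,
    subplots = subplots,
    subplot_rects = rects,
    zones = zones,
    grid = list(n_row = n_row, n_col = n_col, pixel_size_m = px,
                extent_x = extent_x, extent_y = extent_y)
  ), class = "trial_design")

  truth <- structure(list(
    transects = transects,
    subplots = subplot_truth,
    canopy = canopy_tbl
  ), class = "true_field")

  list(design = design, truth = truth)
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "<trial_design> %s: %d transects x %d treatments (%d subplots), max N rate %g kg/ha, grid %d x %d px\n",
    x$trial_id, length(x$transect_ids), nrow(x$treatments),
    nrow(x$subplots), x$max_n_rate, x$grid$n_row, x$grid$n_col
  ))
  invisible(x)
}

#' Render a 4-band reflectance scene for one timing
#'
#' Per-pixel linear spectral mixing: `reflectance = f * canopy +
#' (1 - f) * (r * residue + (1 - r) * soil) + noise`, where `f` is the
#' pixel's canopy fraction (zero outside subplots) and `r` is the
#' trial's residue fraction. Output is in the scaled-integer convention
#' (reflectance times 10,000, clipped to `[0, 10000]`).
#'
#' @param design,truth Output of [generate_trial()].
#' @param timing Timing index present in the design's calendar.
#' @param config The [sim_config()] used to generate the trial.
#' @return A [spectral_scene] of scaled integers.
#' @export
render_scene <- function(design, truth, timing, config) {
  cal <- design$timing_calendar
  if (!timing %in% cal$timing) stop(sprintf("timing %s not in calendar", timing))
  em <- config$endmembers
  bands_needed <- c("B", "G", "R", "NIR")
  if (!all(bands_needed %in% names(em))) stop("endmember table missing a band")

  set.seed(make_seed(config$seed, 101 + design$trial_index * 17 + timing))

  f_by_subplot <- truth$canopy |>
    dplyr::filter(.data$timing == .env$timing)
  f_lookup <- setNames(f_by_subplot$canopy_fraction, f_by_subplot$subplot_id)

  nr <- design$grid$n_row; nc <- design$grid$n_col
  f <- matrix(0, nr, nc)
  z <- design$zones
  f[cbind(z$row, z$col)] <- f_lookup[z$subplot_id]

  r <- design$residue_fraction
  emv <- function(material, band) em[[band]][em$material == material]
  bands <- lapply(setNames(bands_needed, bands_needed), function(b) {
    bg <- r * emv("residue", b) + (1 - r) * emv("soil", b)
    refl <- f * emv("canopy", b) + (1 - f) * bg
    if (config$noise_sd_reflectance > 0) {
      refl <- refl + matrix(rnorm(nr * nc, 0, config$noise_sd_reflectance), nr, nc)
    }
    matrix(as.numeric(round(pmin(pmax(refl * 10000, 0), 10000))), nr, nc)
  })

  spectral_scene(
    B = bands$B, G = bands$G, R = bands$R, NIR = bands$NIR,
    timing = timing, stage = cal$stage[cal$timing == timing],
    rescaled = FALSE, pixel_size_m = design$grid$pixel_size_m,
    origin = c(0, design$grid$extent_y), trial_id = design$trial_id
  )
}

#' Generate a yield-monitor point stream for one trial
#'
#' Points are laid along harvest passes that run the full length of each
#' treatment strip (crossing subplots and the buffers between them, so
#' buffer points naturally fall outside every subplot zone). Clean
#' points carry slowly varying speed (steps under 5%), headings within a
#' few degrees of the pass direction, and moisture well inside the valid
#' range. A configurable fraction of in-subplot points receives injected
#' artifacts -- out-of-range moisture or speed, a >15% speed jump,
#' a heading spike, or a gross yield outlier -- each tagged in the hidden
#' `artifact` column for filter-recall tests. Artifact injection uses a
#' random stream separate from field-truth generation.
#'
#' @inheritParams render_scene
#' @return Tibble of points: `x`, `y`, `pass_id`, `seq`, `heading_deg`,
#'   `speed_mph`, `moisture_pct`, `wet_yield`, plus hidden-truth columns
#'   `subplot_id`, `artifact`.
#' @export
generate_yield_points <- function(design, truth, config) {
  set.seed(make_seed(config$seed, 501 + design$trial_index))

  rects <- design$subplot_rects
  trts <- design$treatments
  n_passes <- config$passes_per_subplot
  # along-pass spacing so each subplot nets ~the target count over all passes
  spacing <- config$subplot_length_m * n_passes / config$yield_points_per_subplot
  extent_y <- design$grid$extent_y
  w <- config$plot_width_m

  exp_yield <- setNames(truth$subplots$expected_yield, truth$subplots$subplot_id)
  trial_mean_yield <- mean(truth$subplots$expected_yield)

  pts <- list()
  for (k in seq_len(nrow(trts))) {
    col_rects <- rects[rects$col_index == k, ]
    x0 <- min(col_rects$xmin)
    for (p in seq_len(n_passes)) {
      ys <- seq(spacing / 2, extent_y - spacing / 2, by = spacing)
      n <- length(ys)
      x <- x0 + (p - 0.5) / n_passes * w + rnorm(n, 0, 0.3)
      # subplot containment (half-open rectangles); NA in buffers
      sub <- rep(NA_character_, n)
      for (j in seq_len(nrow(col_rects))) {
        inside <- ys >= col_rects$ymin[j] & ys < col_rects$ymax[j] &
          x >= col_rects$xmin[j] & x < col_rects$xmax[j]
        sub[inside] <- col_rects$subplot_id[j]
      }
      speed <- numeric(n)
      speed[1] <- runif(1, 4, 5)
      steps <- runif(n, -0.04, 0.04)
      for (i in seq_len(n)[-1]) {
        speed[i] <- min(max(speed[i - 1] * (1 + steps[i]), 2.5), 6.5)
      }
      heading <- rnorm(n, 0, 3) %% 360
      moisture <- pmin(pmax(rnorm(n, 18, 1.5), 12.5), 29)
      adj <- ifelse(is.na(sub), trial_mean_yield, exp_yield[sub]) +
        (if (config$noise_sd_yield > 0) rnorm(n, 0, config$noise_sd_yield) else 0)
      adj <- pmax(adj, 0.1)
      pts[[length(pts) + 1]] <- tibble::tibble(
        trial_id = design$trial_id,
        pass_id = sprintf("%s_c%d_p%d", design$trial_id, k, p),
        seq = seq_len(n), x = x, y = ys,
        heading_deg = heading, speed_mph = speed, moisture_pct = moisture,
        adj_basis_yield = adj, subplot_id = sub,
        artifact = ifelse(is.na(sub), "outside_area", "none")
      )
    }
  }
  points <- purrr::list_rbind(pts)

  # --- artifact injection: separate stream so truth is unperturbed ---
  set.seed(make_seed(config$seed, 901 + design$trial_index))
  inside <- which(points$artifact == "none")
  n_art <- floor(config$artifact_fraction * length(inside))
  if (n_art > 0) {
    idx <- sample(inside, n_art)
    classes <- sample(c("moisture_range", "speed_range", "speed_jump",
                        "heading", "treatment_outlier"), n_art, replace = TRUE)
    # at most one speed jump per pass (keeps clean-point speed sequences clean)
    jump <- which(classes == "speed_jump")
    if (length(jump) > 1) {
      dup <- jump[duplicated(points$pass_id[idx[jump]])]
      classes[dup] <- "moisture_range"
    }
    for (i in seq_along(idx)) {
      j <- idx[i]
      cls <- classes[i]
      if (cls == "moisture_range") {
        points$moisture_pct[j] <- if (runif(1) < 0.5) runif(1, 4, 9.5) else runif(1, 33.5, 40)
      } else if (cls == "speed_range") {
        points$speed_mph[j] <- if (runif(1) < 0.5) runif(1, 0.1, 0.6) else runif(1, 8.5, 12)
      } else if (cls == "speed_jump") {
        tail_i <- which(points$pass_id == points$pass_id[j] & points$seq >= points$seq[j])
        points$speed_mph[tail_i] <- points$speed_mph[tail_i] * 1.25
      } else if (cls == "heading") {
        points$heading_deg[j] <-
          (points$heading_deg[j] + sample(c(-1, 1), 1) * runif(1, 60, 120)) %% 360
      } else if (cls == "treatment_outlier") {
        grp <- points$adj_basis_yield[points$artifact == "none" &
                                        !is.na(points$subplot_id)]
        d <- 6 * max(sd(grp), 0.5)
        points$adj_basis_yield[j] <- points$adj_basis_yield[j] + sample(c(-1, 1), 1) * d
      }
      points$artifact[j] <- cls
    }
  }

  points |>
    dplyr::mutate(
      wet_yield = .data$adj_basis_yield * (1 - 0.15) / (1 - .data$moisture_pct / 100)
    ) |>
    dplyr::select("trial_id", "pass_id", "seq", "x", "y", "heading_deg",
                  "speed_mph", "moisture_pct", "wet_yield",
                  "subplot_id", "artifact")
}

#' Simulate all configured trials
#'
#' Runs [generate_trial()], [render_scene()] (for the requested
#' timings), and [generate_yield_points()] for every trial in the
#' config.
#'
#' @param config A [sim_config()].
#' @param timings Timing indices to render (default: the full calendar).
#' @return List with one element per trial: `design`, `truth`, `scenes`
#'   (named by timing), `yield_points`.
#' @export
simulate_trials <- function(config, timings = config$timings$timing) {
  lapply(seq_along(config$trials), function(i) {
    gt <- generate_trial(config, i)
    scenes <- lapply(setNames(timings, paste0("timing_", timings)), function(tm) {
      render_scene(gt$design, gt$truth, tm, config)
    })
    points <- generate_yield_points(gt$design, gt$truth, config)
    list(design = gt$design, truth = gt$truth, scenes = scenes,
         yield_points = points)
  }) |>
    setNames(vapply(config$trials, `[[`, "", "trial_id"))
}
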