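test_that("trial layout matches the configured design", {
  cfg <- sim_config(seed = 5)
  gt <- generate_trial(cfg, 1)
  expect_equal(nrow(gt$design$subplots), 8 * 5)
  expect_equal(length(gt$design$transect_ids), 8)
  expect_equal(gt$design$max_n_rate, max(cfg$trials[[1]]$treatments$n_rate))
  # each transect holds every treatment exactly once
  per_transect <- dplyr::count(gt$design$subplots, transect_id, treatment)
  expect_true(all(per_transect$n == 1))
  expect_equal(nrow(per_transect), 40)
  # duplicated 50%FNR treatments are distinct subplots with equal rates
  gt2 <- generate_trial(cfg, 2)
  dup <- gt2$design$subplots[grepl("50%FNR", gt2$design$subplots$treatment), ]
  expect_equal(length(unique(dup$subplot_id)), 2 * 8)
  expect_true(all(dup$n_rate == 111))
})

test_that("config validation rejects degenerate designs", {
  bad <- default_trials()
  bad[[1]]$treatments <- tibble::tibble(treatment = c("a", "b"), n_rate = c(50, 100))
  expect_error(sim_config(trials = bad), "3 distinct")
  bad2 <- default_trials()
  bad2[[1]]$treatments$n_rate <- rev(bad2[[1]]$treatments$n_rate)
  expect_error(sim_config(trials = bad2), "sorted")
  expect_error(sim_config(subplot_length_m = -1), "positive")
  bad3 <- default_trials()
  bad3[[2]]$residue_fraction <- 1.4
  expect_error(sim_config(trials = bad3), "residue")
})

test_that("generation is deterministic under the seed", {
  cfg <- sim_config(seed = 99)
  a <- generate_trial(cfg, 1); b <- generate_trial(cfg, 1)
  expect_identical(a$truth, b$truth)
  expect_identical(a$design$zones, b$design$zones)
  sa <- render_scene(a$design, a$truth, 3, cfg)
  sb <- render_scene(b$design, b$truth, 3, cfg)
  expect_identical(sa$bands, sb$bands)
  pa <- generate_yield_points(a$design, a$truth, cfg)
  pb <- generate_yield_points(b$design, b$truth, cfg)
  expect_identical(pa, pb)
  # a different seed changes the draws
  cfg2 <- sim_config(seed = 100)
  c2 <- generate_trial(cfg2, 1)
  expect_false(identical(a$truth$transects$true_aonr, c2$truth$transects$true_aonr))
})

test_that("true yields follow the plateau family and refitting recovers AONR", {
  cfg <- sim_config(seed = 21, noise_sd_yield = 0)
  for (i in seq_along(cfg$trials)) {
    gt <- generate_trial(cfg, i)
    sp <- gt$truth$subplots
    for (tr in unique(sp$transect_id)) {
      d <- sp[sp$transect_id == tr, ]
      d <- d[order(d$n_rate), ]
      # non-decreasing in N, constant beyond the transect's true AONR
      expect_true(all(diff(d$expected_yield) >= -1e-12))
      above <- d$n_rate >= d$true_aonr[1]
      if (sum(above) > 1) {
        expect_lt(diff(range(d$expected_yield[above])), 1e-12)
      }
      # zero-noise refit of the generating family recovers the join
      # point, in the identified regime: at least two distinct rates on
      # the rising limb (with only one, a one-parameter family of
      # curves interpolates exactly and the join is not estimable)
      if (sum(unique(d$n_rate) < d$true_aonr[1]) >= 2 &&
            d$true_aonr[1] < max(d$n_rate)) {
        fit <- fit_quadratic_plateau(d$n_rate, d$expected_yield)
        expect_lt(abs(fit$x0 - d$true_aonr[1]), 0.5)
      }
    }
  }
})

test_that("canopy fraction is non-decreasing across timings 1-4", {
  cfg <- sim_config(seed = 2)
  gt <- generate_trial(cfg, 1)
  wide <- gt$truth$canopy |>
    dplyr::filter(timing <= 4) |>
    dplyr::arrange(subplot_id, timing)
  steps <- wide |>
    dplyr::mutate(d = canopy_fraction - dplyr::lag(canopy_fraction),
                  .by = subplot_id) |>
    dplyr::filter(!is.na(d))
  expect_true(all(steps$d >= 0))
})

test_that("per-pixel NDVI increases strictly with canopy fraction (mixture identity)", {
  em <- default_endmembers()
  canopy <- em[em$material == "canopy", ]
  soil <- em[em$material == "soil", ]
  for (r in c(0, 0.5, 1)) {
    residue <- em[em$material == "residue", ]
    bg <- function(b) r * residue[[b]] + (1 - r) * soil[[b]]
    ndvi <- vapply(seq(0, 1, by = 0.1), function(f) {
      nir <- f * canopy$NIR + (1 - f) * bg("NIR")
      red <- f * canopy$R + (1 - f) * bg("R")
      (nir - red) / (nir + red)
    }, numeric(1))
    expect_true(all(diff(ndvi) > 0))
  }
})

test_that("rendered scenes obey the mixture identities at zero noise", {
  cfg <- sim_config(seed = 3, noise_sd_reflectance = 0)
  gt <- generate_trial(cfg, 1)
  # force full canopy: f = 1 in every subplot
  gt$truth$canopy$canopy_fraction <- 1
  sc <- render_scene(gt$design, gt$truth, 4, cfg)
  em <- cfg$endmembers
  z <- gt$design$zones
  for (b in c("B", "G", "R", "NIR")) {
    inplot <- sc$bands[[b]][cbind(z$row, z$col)]
    expect_true(all(inplot == round(em[[b]][em$material == "canopy"] * 10000)))
  }
  # pure residue background: f = 0, r = 1
  cfg2 <- cfg; cfg2$trials[[1]]$residue_fraction <- 1
  gt2 <- generate_trial(cfg2, 1)
  gt2$truth$canopy$canopy_fraction <- 0
  sc2 <- render_scene(gt2$design, gt2$truth, 1, cfg2)
  for (b in c("B", "G", "R", "NIR")) {
    expect_true(all(sc2$bands[[b]] ==
                      round(em[[b]][em$material == "residue"] * 10000)))
  }
  expect_error(render_scene(gt$design, gt$truth, 99, cfg), "timing")
})

test_that("mean subplot NDVI is non-decreasing in applied N at vegetative timings", {
  cfg <- sim_config(seed = 13, noise_sd_reflectance = 0)
  gt <- generate_trial(cfg, 1)
  for (tm in 1:3) {
    sc <- rescale_scene(render_scene(gt$design, gt$truth, tm, cfg))
    zt <- zonal_means(compute_vi(sc, "NDVI"), gt$design$zones)
    ord <- zt |>
      dplyr::arrange(transect_id, n_rate) |>
      dplyr::mutate(d = mean_value - dplyr::lag(mean_value), .by = transect_id) |>
      dplyr::filter(!is.na(d))
    expect_true(all(ord$d >= -1e-9), label = paste("timing", tm))
  }
})

test_that("scenes round-trip through TIFF exactly", {
  cfg <- small_config(seed = 8)
  gt <- generate_trial(cfg, 1)
  sc <- render_scene(gt$design, gt$truth, 2, cfg)
  path <- tempfile(fileext = ".tif")
  write_scene(sc, path)
  back <- read_scene(path)
  expect_identical(back$bands, sc$bands)
  expect_equal(back$timing, sc$timing)
  expect_equal(back$stage, sc$stage)
  expect_equal(back$pixel_size_m, sc$pixel_size_m)
  unlink(c(path, paste0(path, ".json")))
})

test_that("injected artifacts carry matching hidden labels", {
  cfg <- sim_config(seed = 31, artifact_fraction = 0.10)
  gt <- generate_trial(cfg, 1)
  pts <- generate_yield_points(gt$design, gt$truth, cfg)
  m <- pts[pts$artifact == "moisture_range", ]
  expect_gt(nrow(m), 0)
  expect_true(all(m$moisture_pct < 10 | m$moisture_pct > 33))
  s <- pts[pts$artifact == "speed_range", ]
  expect_true(all(s$speed_mph < 0.7 | s$speed_mph > 8.2))
  o <- pts[pts$artifact == "outside_area", ]
  expect_true(all(is.na(o$subplot_id)))
})

test_that("zero-noise, artifact-free streams reproduce expected yields exactly", {
  cfg <- small_config(seed = 17, noise_sd_yield = 0, noise_sd_reflectance = 0,
                      artifact_fraction = 0)
  gt <- generate_trial(cfg, 1)
  pts <- generate_yield_points(gt$design, gt$truth, cfg)
  cl <- clean_yield(pts, gt$design$subplot_rects)
  m <- dplyr::inner_join(cl$subplot_yield, gt$truth$subplots, by = "subplot_id")
  expect_equal(m$yield, m$expected_yield, tolerance = 1e-12)
})
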