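make_zone <- function() {
  tibble::tibble(
    subplot_id = "s1", transect_id = "T01", treatment = "100%FNR", n_rate = 200,
    xmin = 0, xmax = 20, ymin = 0, ymax = 100
  )
}

make_points <- function(speed = rep(5, 6), moisture = rep(18, 6),
                        heading = rep(0, 6), y = seq(5, 95, length.out = 6)) {
  tibble::tibble(
    pass_id = "p1", seq = seq_along(speed), x = 10, y = y,
    heading_deg = heading, speed_mph = speed, moisture_pct = moisture,
    wet_yield = 10
  )
}

test_that("range filters flag the documented thresholds", {
  pts <- make_points(speed = c(5, 9.0, 5, 0.5, 5, 5),
                     moisture = c(18, 18, 9, 18, 34, 18))
  out <- filter_points(pts, make_zone())
  expect_match(out$flags[2], "speed_range")
  expect_match(out$flags[4], "speed_range")
  expect_match(out$flags[3], "moisture_range")
  expect_match(out$flags[5], "moisture_range")
  # boundary values are kept: 10% and 33% moisture, 0.7 and 8.2 mph
  pts2 <- make_points(speed = c(0.7, 8.2, 5, 5, 5, 5),
                      moisture = c(10, 33, 18, 18, 18, 18))
  out2 <- filter_points(pts2, make_zone())
  expect_false(any(grepl("moisture_range|speed_range", out2$flags[1:2])))
})

test_that("speed jumps above 15% of the previous reading are flagged", {
  pts <- make_points(speed = c(5, 6, 6, 6.5, 6.5, 6.5))
  out <- filter_points(pts, make_zone())
  expect_match(out$flags[2], "speed_jump")   # +20%
  expect_false(grepl("speed_jump", out$flags[4]))  # +8.3%
  expect_false(grepl("speed_jump", out$flags[1]))  # no previous reading
  # the comparison uses the previous recorded point, flagged or not
  pts2 <- make_points(speed = c(5, 9, 5, 5, 5, 5))
  out2 <- filter_points(pts2, make_zone())
  expect_match(out2$flags[2], "speed_range")
  expect_match(out2$flags[2], "speed_jump")
  expect_match(out2$flags[3], "speed_jump")  # 5 vs previous recorded 9
})

test_that("heading and outside-area rules use the pass median and zone geometry", {
  pts <- make_points(heading = c(2, 358, 5, 90, 0, 1))
  out <- filter_points(pts, make_zone())
  expect_match(out$flags[4], "heading")
  expect_false(any(grepl("heading", out$flags[-4])))
  # wrap-around headings near 0/360 are fine
  expect_false(grepl("heading", out$flags[2]))
  pts2 <- make_points(); pts2$x[3] <- 50
  out2 <- filter_points(pts2, make_zone())
  expect_match(out2$flags[3], "outside_area")
  expect_error(filter_points(pts2[, -1], make_zone()), "missing required")
})

test_that("moisture standardization follows dry-matter arithmetic", {
  expect_equal(standardize_moisture(10, 15), 10)
  expect_equal(standardize_moisture(10, 20), 10 * 0.80 / 0.85)
  expect_equal(standardize_moisture(10, 20), 9.41176470588, tolerance = 1e-10)
  expect_equal(standardize_moisture(1, 0), 1 / 0.85)
  expect_error(standardize_moisture(10, 100), "moisture")
})

test_that("treatment outlier screen is single-pass with pre-removal moments", {
  # constructed set: 20 points, one planted beyond 3 sd of the group
  set.seed(4)
  base <- rnorm(20, 10, 0.5)
  planted <- mean(base) + 10 * sd(base)
  df <- tibble::tibble(treatment = "t", y = c(base, planted))
  out <- remove_treatment_outliers(df, y, by = "treatment")
  expect_equal(which(out$outlier), 21)

  # all values equal: sd = 0, nothing removed
  eq <- tibble::tibble(treatment = "t", y = rep(3, 10))
  expect_false(any(remove_treatment_outliers(eq, y)$outlier))

  # group of one passes through with a warning
  one <- tibble::tibble(treatment = c("a", "b", "b", "b"), y = c(1, 2, 2.1, 1.9))
  expect_warning(out1 <- remove_treatment_outliers(one, y), "fewer than 2")
  expect_false(out1$outlier[1])
})

test_that("cleaning conserves counts and is idempotent", {
  cfg <- sim_config(seed = 19, artifact_fraction = 0.08)
  gt <- generate_trial(cfg, 1)
  pts <- generate_yield_points(gt$design, gt$truth, cfg)
  cl <- clean_yield(pts, gt$design$subplot_rects)
  expect_equal(cl$audit$n_retained + cl$audit$n_flagged, cl$audit$n_input)
  expect_equal(nrow(cl$points), nrow(pts))
  # every flagged point has at least one recorded reason
  expect_true(all(nchar(cl$points$flags[!cl$points$retained]) > 0))
  # adjusted yield exists exactly for retained points
  expect_identical(!is.na(cl$points$adjusted_yield), cl$points$retained)

  # idempotence: re-filtering the retained output flags nothing further
  kept <- cl$points[cl$points$retained, ]
  again <- filter_points(kept, gt$design$subplot_rects)
  expect_true(all(again$retained))
})

test_that("range-based filters recover every injected artifact", {
  cfg <- sim_config(seed = 23, artifact_fraction = 0.10,
                    yield_points_per_subplot = 26)
  gt <- generate_trial(cfg, 1)
  pts <- generate_yield_points(gt$design, gt$truth, cfg)
  expect_gt(nrow(pts), 1000)
  out <- filter_points(pts, gt$design$subplot_rects)
  for (cls in c("moisture_range", "speed_range", "speed_jump", "heading",
                "outside_area")) {
    inj <- out$artifact == cls
    expect_gt(sum(inj), 0)
    hit <- vapply(strsplit(out$flags, ","), function(f) cls %in% f, logical(1))
    expect_equal(mean(hit[inj]), 1, label = paste(cls, "recall"))
  }
  # false positives on clean points: none from moisture/heading rules
  clean <- out$artifact == "none"
  expect_false(any(grepl("moisture_range|heading|outside_area",
                         out$flags[clean])))
})
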