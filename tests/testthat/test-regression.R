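test_that("simple OLS statistics match closed-form and lm()", {
  # three points with a known closed-form fit
  out <- fit_vi_yield(c(1, 2, 3), c(1, 2, 2))
  expect_equal(out$slope, 0.5)
  expect_equal(out$r_squared, 0.75)
  # dual route: compare against lm() on random data
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(12); y <- 1 + 0.5 * x + rnorm(12)
    ours <- fit_vi_yield(x, y)
    m <- lm(y ~ x)
    expect_equal(ours$slope, unname(coef(m)[2]), tolerance = 1e-10)
    expect_equal(ours$intercept, unname(coef(m)[1]), tolerance = 1e-10)
    expect_equal(ours$r_squared, summary(m)$r.squared, tolerance = 1e-10)
    expect_equal(ours$p_value, summary(m)$coefficients[2, 4], tolerance = 1e-10)
    # R^2 equals the squared Pearson correlation for simple OLS
    expect_equal(ours$r_squared, cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("perfect fits and degenerate inputs behave per contract", {
  x <- 1:6
  out <- fit_vi_yield(x, 2 + 3 * x)
  expect_equal(out$r_squared, 1)
  expect_equal(out$rmse, 0)
  expect_equal(out$nrmse, 0)
  expect_true(out$significant)

  expect_equal(fit_vi_yield(c(1, 2), c(1, 2))$flag, "too_few_obs")
  expect_equal(fit_vi_yield(rep(2, 5), rnorm(5))$flag, "constant_vi")
})

test_that("nRMSE is invariant to rescaling the yields", {
  set.seed(3)
  x <- runif(10); y <- 2 + x + rnorm(10, 0, 0.2)
  a <- fit_vi_yield(x, y)
  b <- fit_vi_yield(x, 37.5 * y)
  expect_equal(a$nrmse, b$nrmse, tolerance = 1e-12)
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-12)
})

test_that("the significance rule fires at its nominal rate under the null", {
  set.seed(71)
  n_sim <- 2000; n <- 10
  hits <- 0
  for (i in seq_len(n_sim)) {
    r <- fit_vi_yield(rnorm(n), rnorm(n))
    hits <- hits + (r$p_value < 0.10)
  }
  rate <- hits / n_sim
  # 0.10 within ~3.5 binomial standard errors
  expect_lt(abs(rate - 0.10), 3.5 * sqrt(0.1 * 0.9 / n_sim))
})

make_battery_inputs <- function(n_trials = 2, timings = 1:7, seed = 1) {
  set.seed(seed)
  trials <- paste0("F", seq_len(n_trials))
  subplots <- tidyr::expand_grid(trial_id = trials, sp = 1:10) |>
    dplyr::mutate(subplot_id = paste0(trial_id, "_s", sp), yield = rnorm(dplyr::n(), 10))
  zonal <- tidyr::expand_grid(
    trial_id = trials, sp = 1:10, timing = timings, vi_name = vi_names()
  ) |>
    dplyr::mutate(subplot_id = paste0(trial_id, "_s", sp),
                  mean_value = runif(dplyr::n()))
  list(zonal = zonal, yields = subplots[c("trial_id", "subplot_id", "yield")])
}

test_that("the battery enumerates trials x timings x VIs exactly", {
  inp <- make_battery_inputs(n_trials = 3, timings = 1:7)
  res <- run_regression_battery(inp$zonal, inp$yields)
  expect_equal(nrow(res), 3 * 7 * 16)
  expect_equal(sum(res$period == "vegetative"), 144)
  expect_equal(sum(res$period == "reproductive"), 192)

  res1 <- run_regression_battery(
    dplyr::filter(inp$zonal, trial_id == "F1", timing == 1),
    inp$yields, timings = 1
  )
  expect_equal(nrow(res1), 16)

  res3 <- run_regression_battery(inp$zonal, inp$yields, timings = 1:3)
  expect_equal(nrow(res3), 144)

  # combinations with no data survive as flagged placeholders
  gap <- dplyr::filter(inp$zonal, !(trial_id == "F2" & timing == 4))
  resg <- run_regression_battery(gap, inp$yields)
  expect_equal(nrow(resg), 3 * 7 * 16)
  expect_equal(sum(resg$flag == "missing_data", na.rm = TRUE), 16)
  expect_error(run_regression_battery(inp$zonal, inp$yields, timings = 9), "calendar")
})

test_that("battery summaries mirror the period/group/field layout", {
  inp <- make_battery_inputs(n_trials = 3, timings = 1:7, seed = 5)
  res <- run_regression_battery(inp$zonal, inp$yields)
  summ <- summarize_battery(res)
  veg_nir <- summ[summ$period == "vegetative" & summ$vi_group == "NIR" &
                    summ$trial_id == "ALL", ]
  expect_equal(veg_nir$models, 72)  # 3 fields x 3 timings x 8 NIR VIs
  all_all <- summ[summ$period == "vegetative" & summ$vi_group == "ALL" &
                    summ$trial_id == "ALL", ]
  expect_equal(all_all$models, 144)
  # significant counts add across the two groups
  veg_rgb <- summ[summ$period == "vegetative" & summ$vi_group == "RGB" &
                    summ$trial_id == "ALL", ]
  expect_equal(all_all$significant_models,
               veg_nir$significant_models + veg_rgb$significant_models)

  # no significant models: empty ranges
  null_res <- res |>
    dplyr::mutate(significant = FALSE)
  s0 <- summarize_battery(null_res)
  expect_true(all(s0$significant_models == 0))
  expect_true(all(is.na(s0$min_r2)))

  # a single significant model collapses the range
  one <- res |>
    dplyr::mutate(significant = dplyr::row_number() == 1)
  s1 <- summarize_battery(one)
  r <- s1[s1$significant_models == 1, ]
  expect_equal(r$min_r2, r$max_r2)
})
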