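#' Akaike information criterion for a least-squares fit
#'
#' `AIC = n * ln(RSS/n) + 2 * (p + 1)`, counting the error variance as
#' an estimated parameter alongside the `p` curve parameters. A perfect
#' fit (`RSS = 0`) returns `-Inf` so it always wins model comparison.
#'
#' @param rss Residual sum of squares.
#' @param n_obs Number of observations.
#' @param n_params Number of curve parameters (3 for both plateau
#'   families).
#' @return The AIC value.
#' @export
aic_ls <- function(rss, n_obs, n_params) {
  if (rss <= 0) return(-Inf)
  n_obs * log(rss / n_obs) + 2 * (n_params + 1)
}

# Conditional OLS of y on a single regressor z (closed form).
# Returns intercept, slope, rss. Constant z collapses to intercept-only.
ols1 <- function(z, y) {
  zb <- mean(z); yb <- mean(y)
  szz <- sum((z - zb)^2)
  if (szz == 0) {
    return(list(a = yb, b = 0, rss = sum((y - yb)^2)))
  }
  b <- sum((z - zb) * (y - yb)) / szz
  a <- yb - b * zb
  list(a = a, b = b, rss = sum((y - (a + b * z))^2))
}

new_plateau_fit <- function(family, a, b, c, x0, plateau, rss, tss, n_obs,
                            x, y, converged = TRUE, boundary = FALSE) {
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  # an RSS at machine-precision level is a perfect fit; flooring it to
  # zero makes two interpolating fits an exact AIC tie instead of an
  # arbitrary comparison of rounding noise
  rss_eff <- if (rss <= 1e-10 * tss) 0 else rss
  structure(list(
    family = family, a = a, b = b, c = c, x0 = x0, plateau = plateau,
    rss = rss, tss = tss, r_squared = r2,
    aic = aic_ls(rss_eff, n_obs, 3), n_obs = n_obs,
    converged = converged, boundary = boundary, x = x, y = y
  ), class = "plateau_fit")
}

check_plateau_input <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("plateau fits need at least 4 observations")
  if (length(unique(x)) < 3) stop("plateau fits need at least 3 distinct x values")
  list(x = x, y = y)
}

# Profile the RSS over a dense grid of candidate join points (the
# conditional problem given x0 is exact OLS on a single regressor, so
# the whole grid is vectorized), then polish the winning bracket and
# every near-tied bracket with a 1-D optimizer. The dense grid locates
# the global basin -- the profile is piecewise smooth with kinks at the
# data knots and can carry several close local minima -- and the
# optimizer supplies the final precision.
profile_join <- function(x, y, candidates, basis) {
  candidates <- sort(candidates)
  keep <- c(TRUE, diff(candidates) > 1e-12 * diff(range(candidates)))
  candidates <- candidates[keep]
  n <- length(x)
  Z <- basis(x, candidates)                  # n x m conditional regressors
  # explicitly centered OLS with explicit residuals: stable even when a
  # candidate join point makes the regressor nearly constant
  Zc <- Z - rep(colMeans(Z), each = n)
  yc <- y - mean(y)
  den <- colSums(Zc^2)
  num <- colSums(Zc * yc)
  bb <- ifelse(den > 0, num / den, 0)
  rss_c <- colSums((yc - Zc * rep(bb, each = n))^2)

  i <- which.min(rss_c)
  best_x0 <- candidates[i]; best_rss <- rss_c[i]
  prof <- function(x0) ols1(basis(x, x0), y)$rss
  m <- length(candidates)
  near <- which(rss_c <= best_rss * (1 + 1e-6) + 1e-300)
  brackets <- unique(pmax(pmin(c(near - 1, near), m - 1), 1))
  for (j in brackets) {
    op <- optimize(prof, interval = c(candidates[j], candidates[j + 1]),
                   tol = .Machine$double.eps^0.5)
    if (op$objective < best_rss) {
      best_x0 <- op$minimum; best_rss <- op$objective
    }
  }
  list(x0 = best_x0, rss = best_rss)
}

#' Fit a linear-plateau response curve
#'
#' `y = a + b * min(x, x0)`: linear rise to the join point `x0`, flat
#' beyond. Fitted by profiling the join point -- conditional on `x0` the
#' model is exact OLS on `min(x, x0)` -- over a dense candidate grid
#' (2001 values plus the observed rates, evaluated in one vectorized
#' pass), then polishing the winning bracket with a bounded 1-D
#' optimizer. `x0` is constrained to `[min(x), max(x)]`; a join at the
#' maximum tested rate is reported with `boundary = TRUE`.
#'
#' @param x N rates (kg/ha).
#' @param y Response values (a vegetation index, or yield in Mg/ha).
#' @return A `plateau_fit` object; see [tidy.plateau_fit()] and
#'   [glance.plateau_fit()].
#' @export
#' @examples
#' f <- fit_linear_plateau(c(0, 1, 2, 3, 4), 1 + 2 * pmin(c(0, 1, 2, 3, 4), 3))
#' glance(f)
fit_linear_plateau <- function(x, y) {
  d <- check_plateau_input(x, y); x <- d$x; y <- d$y
  basis <- function(x, x0) outer(x, x0, pmin)
  candidates <- unique(c(seq(min(x), max(x), length.out = 2001), x))
  best <- profile_join(x, y, candidates, basis)
  fit <- ols1(pmin(x, best$x0), y)
  new_plateau_fit(
    family = "linear_plateau", a = fit$a, b = fit$b, c = NA_real_,
    x0 = best$x0, plateau = fit$a + fit$b * best$x0,
    rss = best$rss, tss = sum((y - mean(y))^2), n_obs = length(x),
    x = x, y = y,
    boundary = best$x0 >= max(x) - 1e-8 * diff(range(x))
  )
}

#' Fit a quadratic-plateau response curve
#'
#' The smooth-vertex parameterization: `y = a + b*x + c*x^2` for
#' `x < x0` and constant at the vertex value beyond, with
#' `x0 = -b/(2c)` so the curve and its first derivative are continuous
#' at the join. Conditional on `x0` the model is linear in `(a, b)`
#' through the regressor `g(x) = x - x^2/(2 x0)` (for `x < x0`; `x0/2`
#' beyond), so the join is profiled exactly as in
#' [fit_linear_plateau()]. A convex solution (`c >= 0`) is returned
#' as-is and rejected later at screening.
#'
#' @inheritParams fit_linear_plateau
#' @return A `plateau_fit` object.
#' @export
#' @examples
#' x <- 0:4
#' f <- fit_quadratic_plateau(x, ifelse(x < 2, 4 * x - x^2, 4))
#' glance(f) # join at 2, plateau 4
fit_quadratic_plateau <- function(x, y) {
  d <- check_plateau_input(x, y); x <- d$x; y <- d$y
  basis <- function(x, x0) {
    outer(x, x0, function(xx, vv) ifelse(xx < vv, xx - xx^2 / (2 * vv), vv / 2))
  }
  lo <- max(min(x[x > 0], na.rm = TRUE) / 2, 0.02 * max(x))
  hi <- 1.5 * max(x)  # a vertex beyond the tested range is a valid
                      # outcome; the exceeds-max rule judges it later
  candidates <- unique(c(seq(lo, hi, length.out = 2001), x[x >= lo]))
  best <- profile_join(x, y, candidates, basis)
  fit <- ols1(ifelse(x < best$x0, x - x^2 / (2 * best$x0), best$x0 / 2), y)
  cc <- -fit$b / (2 * best$x0)
  tss <- sum((y - mean(y))^2)

  # unconstrained parabola: when the data are convex (c >= 0) it beats
  # every concave plateau curve and is the least-squares (a, b, c)
  # answer; report it so screening can reject the curvature
  Xq <- cbind(1, x, x^2)
  qc <- tryCatch(qr.coef(qr(Xq), y), error = function(e) NULL)
  if (!is.null(qc) && all(is.finite(qc))) {
    rss_q <- sum((y - Xq %*% qc)^2)
    if (qc[3] >= 0 && rss_q < best$rss) {
      return(new_plateau_fit(
        family = "quadratic_plateau", a = qc[[1]], b = qc[[2]], c = qc[[3]],
        x0 = NA_real_, plateau = NA_real_,
        rss = rss_q, tss = tss, n_obs = length(x), x = x, y = y,
        boundary = FALSE
      ))
    }
  }

  new_plateau_fit(
    family = "quadratic_plateau", a = fit$a, b = fit$b, c = cc,
    x0 = best$x0, plateau = fit$a + fit$b * best$x0 / 2,
    rss = best$rss, tss = tss, n_obs = length(x),
    x = x, y = y,
    boundary = best$x0 >= max(x) - 1e-8 * diff(range(x))
  )
}

#' Predict from a plateau fit
#' @param object A `plateau_fit`.
#' @param newdata Numeric vector of N rates (default: the fitted rates).
#' @param ... Unused.
#' @return Predicted response values.
#' @export
predict.plateau_fit <- function(object, newdata = object$x, ...) {
  x <- newdata
  if (object$family == "linear_plateau") {
    object$a + object$b * pmin(x, object$x0)
  } else if (is.na(object$x0)) {
    # convex solution: a plain parabola, no plateau in range
    object$a + object$b * x + object$c * x^2
  } else {
    ifelse(x < object$x0,
           object$a + object$b * x + object$c * x^2,
           object$a + object$b * object$x0 + object$c * object$x0^2)
  }
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat(sprintf(
    "<plateau_fit: %s> join x0 = %.2f, plateau = %.4g, R^2 = %.3f, AIC = %.2f (n = %d)%s\n",
    x$family, x$x0, x$plateau, x$r_squared, x$aic, x$n_obs,
    if (x$boundary) " [join at boundary]" else ""
  ))
  invisible(x)
}

#' Tidy a plateau fit
#' @param x A `plateau_fit`.
#' @param ... Unused.
#' @return Tibble of parameter estimates (`term`, `estimate`).
#' @export
tidy.plateau_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c", "x0", "plateau"),
    estimate = c(x$a, x$b, x$c, x$x0, x$plateau)
  )
}

#' One-row summary of a plateau fit
#' @param x A `plateau_fit`.
#' @param ... Unused.
#' @return One-row tibble: family, join point (the candidate AONR),
#'   plateau value, fit statistics, convergence and boundary flags.
#' @export
glance.plateau_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, x0 = x$x0, plateau = x$plateau,
    r_squared = x$r_squared, rss = x$rss, aic = x$aic,
    n_obs = x$n_obs, converged = x$converged, boundary = x$boundary
  )
}

#' Plot a plateau fit over its data
#' @param object A `plateau_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plateau_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(min(object$x), max(object$x), length.out = 200))
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(tibble::tibble(x = object$x, y = object$y),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$x0, linetype = "dashed") +
    ggplot2::labs(
      x = "N rate (kg/ha)", y = "response",
      title = sprintf("%s fit, join at %.1f kg/ha", object$family, object$x0)
    ) +
    ggplot2::theme_minimal()
}
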