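# Independent oracles used across test files.

# Exhaustive profiling oracle for the linear-plateau fit: a dense grid
# of candidate join points with closed-form conditional OLS at each.
# Grid-only (no local optimizer), so it is independent of the fitting
# path in fit_linear_plateau().
# Two stages of pure grid enumeration: a global sweep, then a 20001-point
# sweep across the bracket around the global argmin (grid resolution
# ~1e-9 of the range, removing discretization error at the 1e-8 level).
lp_profile_oracle <- function(x, y, n_grid = 50001) {
  sweep <- function(x0s) {
    n <- length(x)
    Z <- outer(x, x0s, pmin)                   # n x n_grid
    Zc <- Z - rep(colMeans(Z), each = n)       # centered: numerically stable
    yc <- y - mean(y)
    den <- colSums(Zc^2)
    num <- colSums(Zc * yc)
    b <- ifelse(den > 0, num / den, 0)
    rss <- colSums((yc - Zc * rep(b, each = n))^2)
    i <- which.min(rss)
    list(x0 = x0s[i], rss = rss[i], i = i, x0s = x0s)
  }
  # data knots enter both stages: the profile has kink minima exactly there
  s1 <- sweep(sort(unique(c(seq(min(x), max(x), length.out = n_grid), x))))
  lo <- s1$x0s[max(s1$i - 1, 1)]
  hi <- s1$x0s[min(s1$i + 1, length(s1$x0s))]
  s2 <- sweep(sort(unique(c(seq(lo, hi, length.out = 20001), x[x >= lo & x <= hi]))))
  if (s2$rss < s1$rss) list(x0 = s2$x0, rss = s2$rss)
  else list(x0 = s1$x0, rss = s1$rss)
}

# Scalar per-pixel VI evaluator: formulas typed independently of the
# vectorized implementation, evaluated one pixel at a time.
scalar_vi <- function(vi, B, G, R, NIR) {
  div <- function(n, d) if (d == 0) NA_real_ else n / d
  switch(vi,
    EXG   = 2 * G - R - B,
    EXR   = 1.4 * R - B,
    VDVI  = div(2 * G - B - R, 2 * G + B + R),
    PPRB  = div(G - B, G + B),
    VARI  = div(G - R, G + R - B),
    VIG   = div(G - R, G + R),
    DVI   = G - R,
    GREEN = G,
    NDVI  = div(NIR - R, NIR + R),
    GNDVI = div(NIR - G, NIR + G),
    OSAVI = div(NIR - R, NIR + R + 0.16),
    SAVI  = (1 + 0.5) * div(NIR - R, NIR + R + 0.5),
    CVI   = div(NIR, G) * div(R, G),
    RDVI  = div(NIR - R, sqrt(NIR + R)),
    GARI  = div(NIR - (G - 1.7 * (B - R)), NIR + (G - 1.7 * (B - R))),
    EVI2  = div(2.5 * (NIR - R), NIR + 2.4 * R + 1)
  )
}

# A small, fast simulation config for pipeline-level tests.
small_config <- function(seed = 11, ...) {
  sim_config(
    trials = default_trials()[1],
    transects_per_trial = 4,
    yield_points_per_subplot = 12,
    seed = seed,
    ...
  )
}

# Random 4-band test scene (reflectance scale), already rescaled.
random_scene <- function(n = 16, seed = 1) {
  set.seed(seed)
  mk <- function(lo, hi) matrix(runif(n * n, lo, hi), n, n)
  spectral_scene(B = mk(0, 0.3), G = mk(0, 0.4), R = mk(0, 0.4),
                 NIR = mk(0, 0.9), timing = 1L, stage = "V7-V8",
                 rescaled = TRUE)
}
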