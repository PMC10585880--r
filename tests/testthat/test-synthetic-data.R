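# Synthetic weekly death-count generator.

test_that("scenario parameter sets hold the calibrated constants", {
  p <- base_case_params()
  expect_equal(p$beta0, 10.11)
  expect_equal(p$beta1, -7.36e-5)
  expect_equal(p$beta2, 3.04e-9)
  expect_equal(p$A, 0.07)
  expect_equal(p$phi, -0.61)
  expect_equal(p$size, 1000)
  expect_equal(p$winter$probability, 0.45)
  expect_equal(c(p$winter$height_min, p$winter$height_max), c(0.11, 0.33))
  expect_equal(c(p$winter$width_min, p$winter$width_max), c(8.41, 35.36))
  expect_equal(c(p$winter$week_lo, p$winter$week_hi), c(1L, 11L))
  expect_equal(p$summer$probability, 0.40)
  expect_equal(c(p$summer$height_min, p$summer$height_max), c(0.10, 0.24))
  expect_equal(c(p$summer$width_min, p$summer$width_max), c(0.86, 9.24))
  expect_equal(c(p$summer$week_lo, p$summer$week_hi), c(26L, 37L))

  expect_identical(scenario_params("quadratic")[names(p) != "name"],
                   p[names(p) != "name"])
  lin <- scenario_params("linear")
  expect_equal(c(lin$beta1, lin$beta2), c(-7.36e-5, 0))
  con <- scenario_params("constant")
  expect_equal(c(con$beta1, con$beta2), c(0, 0))
  nm <- scenario_params("nonmonotone")
  expect_equal(c(nm$beta0, nm$beta1, nm$beta2), c(10, 9.5e-5, -3e-9))
  expect_error(scenario_params("cubic"))
})

test_that("peak sampling follows the peak laws", {
  g <- week_grid(2000, 2019)

  # zero occurrence probability means no peaks, ever
  p0 <- base_case_params()
  p0$winter$probability <- 0
  p0$summer$probability <- 0
  set.seed(1)
  expect_equal(nrow(sample_peaks(g, p0)), 0)

  # bounds and expectation: 20 years x p = 0.45 winter peaks on average
  set.seed(2)
  p <- base_case_params()
  counts <- replicate(400, {
    pk <- sample_peaks(g, p)
    wk <- pk[pk$season == "winter", ]
    stopifnot(all(wk$width >= 8.41 & wk$width <= 35.36),
              all(wk$height >= 0.11 & wk$height <= 0.33),
              all(pk$height[pk$season == "summer"] >= 0.10),
              all(pk$width[pk$season == "summer"] <= 9.24))
    nrow(wk)
  })
  # Binomial(20, .45): mean 9, SE of the mean over 400 reps ~ 0.111
  expect_lt(abs(mean(counts) - 9), 3 * sqrt(20 * 0.45 * 0.55 / 400))

  # at most one peak per season and year
  set.seed(3)
  pk <- sample_peaks(g, p)
  expect_false(any(duplicated(pk[, c("season", "year")])))
})

test_that("mean curve combines trend, seasonality and peak kernels", {
  g <- week_grid(2010, 2012)

  # constant trend, no seasonality, no peaks
  p <- peakless_params("constant", A = 0)
  expect_equal(mean_curve(g, p), rep(exp(10.11), nrow(g)), tolerance = 1e-12)

  # a peak evaluated at its own mode adds exactly its height to log(mu)
  peak <- data.frame(season = "winter", year = 2011,
                     location = g$t_days[80], width = 20, height = 0.2)
  mu <- mean_curve(g, p, peak)
  expect_equal(log(mu[80]) - 10.11, 0.2, tolerance = 1e-12)
  # ... and never more than its height anywhere, never negative
  bump <- log(mu) - 10.11
  expect_true(all(bump >= 0 & bump <= 0.2 + 1e-12))
  # peaks only ever increase the mean curve
  expect_true(all(mu >= mean_curve(g, p)))
  # tails reach across year boundaries
  expect_gt(bump[53], 0)

  # seasonal maximum sits near week 6 (w = -phi / 2 pi ~ 0.0971)
  ps <- peakless_params("constant")
  mu_s <- mean_curve(g[g$iso_year == 2011, ], ps)
  expect_equal(which.max(mu_s), 6)
})

test_that("simulation is reproducible and negative-binomial", {
  s1 <- simulate_mortality("linear", seed = 7)
  s2 <- simulate_mortality("linear", seed = 7)
  expect_identical(s1, s2)

  expect_true(all(s1$deaths >= 0))
  expect_true(all(s1$deaths == round(s1$deaths)))
  expect_true(all(s1$mu > 0))

  # moment check: constant mu = exp(10.11), size 1000 =>
  # var = mu + mu^2 / 1000 ~ 632e3; ~50k draws puts the sample variance
  # within a few percent of that
  p <- peakless_params("constant", A = 0)
  g <- grid_2000_2023()
  set.seed(11)
  draws <- unlist(replicate(40, simulate_mortality(p, grid = g)$deaths,
                            simplify = FALSE))
  mu <- exp(10.11)
  expect_equal(var(draws), mu + mu^2 / 1000, tolerance = 0.05)
  expect_equal(mean(draws), mu, tolerance = 0.01)
})

test_that("simulated counts track the deterministic trend when peaks are off", {
  # empirical mean of replicated counts converges to exp(b0 + b1 t + b2 t2)
  p <- peakless_params("quadratic", A = 0)
  g <- week_grid(2018, 2019)
  set.seed(12)
  m <- rowMeans(replicate(300, simulate_mortality(p, grid = g)$deaths))
  truth <- exp(10.11 - 7.36e-5 * g$t_days + 3.04e-9 * g$t_days^2)
  expect_lt(max(abs(m - truth) / truth), 0.02)
})
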