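# The four baseline predictors.

all_methods <- list(
  list(method = "average"),
  list(method = "linear"),
  list(method = "who", k = 3),
  list(method = "ai", tkpy = 1 / 7))

test_that("all methods reproduce a constant series exactly", {
  g <- grid_2000_2023()
  s <- data.frame(g, deaths = 20000L)
  for (cf in all_methods) {
    f <- suppressWarnings(do.call(baseline_fit, c(list(s), cf)))
    p <- predict(f, years = 2020:2023)
    # 52 x 20000 in ordinary years, 53 x 20000 in the long year 2020
    expect_equal(p$predicted[p$year == 2021], 1040000,
                 tolerance = 1e-3)
    expect_equal(p$predicted[p$year == 2020] / p$predicted[p$year == 2021],
                 53 / 52, tolerance = 1e-6)
    expect_true(all(p$predicted > 0))
  }
})

test_that("predicted 53-week years scale as 53/52 on simulated constant data", {
  s <- cached("const_series", simulate_mortality("constant", seed = 31))
  for (cf in all_methods) {
    f <- do.call(baseline_fit, c(list(s), cf))
    p <- predict(f, years = 2020:2021)
    expect_equal(p$predicted[1] / p$predicted[2], 53 / 52, tolerance = 0.01)
  }
})

test_that("the WHO trend extrapolates linearly beyond the training window", {
  s <- base_series()
  f <- baseline_fit(s, "who", start_year = 2000, k = 10)
  fut <- week_grid(2020, 2023)
  tm <- predict(f, newdata = fut, type = "terms")
  trend <- tm[, grep("thin-plate", colnames(tm))]
  # equally spaced future grid: second differences of the trend vanish
  expect_lt(max(abs(diff(trend, differences = 2))), 1e-8)
})

test_that("the AI trend switches to a straight line for short windows and small tkpy", {
  s <- base_series()

  # fewer than 7 training years: linear regardless of tkpy
  f5 <- baseline_fit(s, "ai", start_year = 2015, tkpy = 1 / 4)
  expect_equal(f5$trend_type, "linear")

  # one trend degree of freedom (floor(20/12) = 1): linear
  f12 <- baseline_fit(s, "ai", start_year = 2000, tkpy = 1 / 12)
  expect_equal(f12$trend_type, "linear")

  # enough years and degrees of freedom: natural-cubic trend ...
  f4 <- baseline_fit(s, "ai", start_year = 2000, tkpy = 1 / 4)
  expect_equal(f4$trend_type, "natural-cubic")
  expect_equal(ncol(f4$trend_basis$values), 5)  # floor(20/4) = 5 df

  # ... which still extrapolates linearly (natural spline boundary)
  for (f in list(f5, f4)) {
    fut <- week_grid(2020, 2023)
    # rebuild the trend contribution alone (without the periodic harmonics)
    trend <- if (f$trend_type == "linear")
      coef(f)[2] * fut$t_days
    else
      eval_basis(f$trend_basis, fut$t_days) %*%
        coef(f)[1 + seq_len(ncol(f$trend_basis$values))]
    expect_lt(max(abs(diff(as.numeric(trend), differences = 2))), 1e-8)
  }
})

test_that("hyperparameters are validated against the method", {
  s <- base_series()
  expect_error(baseline_fit(s, "average", k = 3), "who")
  expect_error(baseline_fit(s, "linear", tkpy = 1 / 7), "ai")
  expect_error(baseline_fit(s, "who", start_year = 2021), "exceed")
  s_short <- s[s$iso_year >= 2005, ]
  expect_error(baseline_fit(s_short, "linear", start_year = 2000),
               "training years")
})

test_that("the investigated method grid matches the study design", {
  g <- method_grid()
  expect_equal(nrow(g), 5 + 4 + 4 * 5 + 4 * 5)
  expect_true(any(g$method == "ai" & g$start_year == 2000 &
                    abs(g$tkpy - 1 / 7) < 1e-12))
  expect_true(any(g$method == "who" & g$start_year == 2015 & g$k == 10))
  expect_true(any(g$method == "who" & g$k == 3))
  expect_true(all(is.na(g$k[g$method == "average"])))
  expect_true(all(is.na(g$tkpy[g$method == "average"])))
  expect_equal(sort(unique(g$start_year[g$method == "average"])),
               c(2000, 2005, 2010, 2015, 2019))
})

test_that("averaging overpredicts a declining trend; the linear fit does not", {
  # on the declining linear scenario, the average of earlier (higher)
  # years overshoots the target years: bias = mean(actual - predicted) < 0;
  # the correctly specified linear method is unbiased
  n <- 30
  bias_avg <- bias_lin <- numeric(n)
  for (r in seq_len(n)) {
    s <- simulate_mortality("linear", seed = 4000 + r)
    act <- yearly_totals(s, 2020:2023)$deaths
    pa <- predict(baseline_fit(s, "average", start_year = 2000))
    pl <- predict(baseline_fit(s, "linear", start_year = 2000))
    bias_avg[r] <- mean((act - pa$predicted) / 1000)
    bias_lin[r] <- mean((act - pl$predicted) / 1000)
  }
  expect_lt(mean(bias_avg), 0)
  expect_lt(mean(bias_avg) + 3 * sd(bias_avg) / sqrt(n), 0)
  expect_lt(abs(mean(bias_lin)), 3 * sd(bias_lin) / sqrt(n))
})
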