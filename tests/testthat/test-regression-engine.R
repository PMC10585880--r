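# Penalized count-GLM engine.

make_training <- function(seed = 21, years = 2010:2019) {
  simulate_mortality("linear", start_year = min(years),
                     end_year = max(years), seed = seed)
}

test_that("an unpenalized fit (lambda = 0) matches the plain GLM oracle", {
  s <- make_training()
  b <- cyclic_cubic_basis(s$w, k = 10)
  f <- pgam(s$deaths, parametric = cbind(t = s$t_days), smooths = list(b),
            family = "quasipoisson", sp = 0)
  oracle <- glm(s$deaths ~ s$t_days + b$values, family = quasipoisson())
  expect_equal(predict(f, parametric = cbind(s$t_days),
                       smooth_x = list(s$w)),
               unname(fitted(oracle)), tolerance = 1e-6)
  expect_equal(f$pearson_dispersion,
               summary(oracle)$dispersion, tolerance = 1e-4)
})

test_that("a huge lambda shrinks the trend smooth to the affine family", {
  s <- make_training(22)
  bt <- tprs_basis(s$t_days, k = 10)
  bw <- cyclic_cubic_basis(s$w, k = 10)
  f <- pgam(s$deaths, smooths = list(bt, bw), family = "quasipoisson",
            sp = c(1e12, 1e12))
  # at lambda -> infinity only the penalty null spaces survive: affine
  # trend + (for the centered cyclic basis) nothing
  oracle <- glm(s$deaths ~ s$t_days, family = quasipoisson())
  expect_equal(predict(f, smooth_x = list(s$t_days, s$w)),
               unname(fitted(oracle)), tolerance = 1e-4)
})

test_that("the engine recovers the parameters of a log-linear NB model", {
  set.seed(23)
  n <- 2000
  x <- runif(n, -1, 1)
  beta <- c(8.5, 0.5)
  mu <- exp(beta[1] + beta[2] * x)
  y <- rnbinom(n, mu = mu, size = 1000)
  f <- pgam(y, parametric = cbind(x = x), family = "nb")
  se <- sqrt(diag(vcov(f$fit)))
  expect_lt(abs(f$coefficients[1] - beta[1]), 3 * se[1])
  expect_lt(abs(f$coefficients[2] - beta[2]), 3 * se[2])
  expect_lt(abs(f$theta - 1000) / 1000, 0.25)
  expect_true(f$converged)
  expect_gt(f$iterations, 0)
})

test_that("REML-selected fits are invariant to penalty rescaling", {
  s <- make_training(24)
  b1 <- cyclic_cubic_basis(s$w, k = 10)
  b2 <- b1
  b2$penalty$values <- 100 * b1$penalty$values
  f1 <- pgam(s$deaths, smooths = list(b1), family = "nb")
  f2 <- pgam(s$deaths, smooths = list(b2), family = "nb")
  p1 <- predict(f1, smooth_x = list(s$w))
  p2 <- predict(f2, smooth_x = list(s$w))
  expect_equal(p1, p2, tolerance = 1e-6)
  expect_equal(f2$lambdas * 100, f1$lambdas, tolerance = 1e-2)
})

test_that("quasi-Poisson and NB fits coincide on near-Poisson data", {
  g <- week_grid(2012, 2019)
  p <- peakless_params("linear")
  set.seed(25)
  mu <- mean_curve(g, p)
  y <- rpois(nrow(g), mu)  # no overdispersion at all
  b <- cyclic_cubic_basis(g$w, k = 10)
  fq <- pgam(y, parametric = cbind(t = g$t_days), smooths = list(b),
             family = "quasipoisson")
  fn <- pgam(y, parametric = cbind(t = g$t_days), smooths = list(b),
             family = "nb")
  pq <- predict(fq, parametric = cbind(g$t_days), smooth_x = list(g$w))
  pn <- predict(fn, parametric = cbind(g$t_days), smooth_x = list(g$w))
  expect_lt(max(abs(pq - pn) / pq), 1e-3)
  expect_equal(fq$pearson_dispersion, 1, tolerance = 0.1)
})

test_that("effective degrees of freedom stay between null space and basis dimension", {
  s <- make_training(26)
  bt <- tprs_basis(s$t_days, k = 10)
  bw <- cyclic_cubic_basis(s$w, k = 10)
  f <- pgam(s$deaths, smooths = list(bt, bw), family = "nb")
  expect_gte(f$edf[1], 1 - 1e-6)        # centered tp: affine direction left
  expect_lte(f$edf[1], ncol(bt$values) + 1e-6)
  expect_gte(f$edf[2], 0 - 1e-6)
  expect_lte(f$edf[2], ncol(bw$values) + 1e-6)
  expect_length(f$lambdas, 2)
  expect_true(all(f$lambdas >= 0))
})

test_that("input validation and prediction contracts hold", {
  expect_error(pgam(c(1, -2, 3)), "nonnegative")
  expect_error(pgam(c(1, 2.5, 3)), "integer")

  set.seed(27)
  y <- rpois(50, 20)
  f <- pgam(y, family = "nb")
  # intercept-only model predicts exp(coef) everywhere
  expect_equal(predict(f, parametric = NULL, smooth_x = list())[1],
               exp(unname(coef(f)[1])))

  s <- make_training(28)
  b <- cyclic_cubic_basis(s$w, k = 10)
  fs <- pgam(s$deaths, parametric = cbind(t = s$t_days), smooths = list(b),
             family = "quasipoisson")
  # predicting on the training rows reproduces the in-sample fit
  expect_equal(predict(fs, parametric = cbind(s$t_days),
                       smooth_x = list(s$w)),
               unname(fitted(fs$fit)), tolerance = 1e-10)
  expect_error(predict(fs, parametric = cbind(s$t_days, s$t_days),
                       smooth_x = list(s$w)), "columns")
  expect_error(predict(fs, parametric = cbind(s$t_days),
                       smooth_x = list()), "one covariate vector")
})
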