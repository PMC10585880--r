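# The four baseline-mortality predictors.
#
# Each maps a training window of a weekly death series to predicted weekly
# expected deaths (and hence yearly totals) for future target years:
#
#   average -- NB fit of log mu = b0 + f_cc(w): the seasonal average of the
#              training years, extrapolated as a constant;
#   linear  -- NB fit of log mu = b0 + b1 t + f_cc(w);
#   who     -- NB fit of log mu = f_tp(t) + f_cc(w), thin-plate trend with
#              basis dimension k, REML smoothness selection (the WHO-style
#              model; its second-derivative penalty makes the forecast a
#              linear extrapolation of the trend);
#   ai      -- quasi-Poisson fit of log mu = b0 + f_nc(t) + two sine/cosine
#              harmonic pairs in w (the Acosta-Irizarry-style model).  The
#              natural-cubic trend has floor(tkpy * training years) degrees
#              of freedom; when that is 1, or when the training window is
#              shorter than 7 years, the trend is simply linear in t.

harmonic_design <- function(w) {
  cbind(`sin1` = sin(2 * pi * w), `cos1` = cos(2 * pi * w),
        `sin2` = sin(4 * pi * w), `cos2` = cos(4 * pi * w))
}

#' Fit a baseline mortality model to a weekly death series
#'
#' Fits one of the four baseline predictors on the training window
#' `start_year..train_end` of `series`.  The fitted object predicts weekly
#' expected deaths on any ISO-week grid (honouring 53-week years) via
#' [predict.baseline_fit()].
#'
#' @param series a weekly series: data frame with the [week_grid()] columns
#'   plus `deaths` ([simulate_mortality()] output or
#'   [read_weekly_series()] import).
#' @param method `"average"`, `"linear"`, `"who"` or `"ai"`.
#' @param start_year first training year (the window is
#'   `start_year..train_end`).
#' @param k thin-plate trend basis dimension; `"who"` only.
#' @param tkpy trend knots per year (e.g. `1/7`); `"ai"` only.
#' @param train_end last training year (default 2019).
#' @param seasonal_k cyclic seasonal basis dimension for the NB methods
#'   (default 10).
#' @return an object of class `baseline_fit`.
#' @seealso [fit_and_predict()] for the one-shot fit-and-total wrapper,
#'   [method_grid()] for the investigated hyperparameter grid.
#' @export
#' @examples
#' s <- simulate_mortality("linear", seed = 1)
#' f <- baseline_fit(s, "who", start_year = 2000, k = 3)
#' predict(f, years = 2020:2023)
baseline_fit <- function(series, method = c("average", "linear", "who", "ai"),
                         start_year = 2000, k = NULL, tkpy = NULL,
                         train_end = 2019, seasonal_k = 10) {
  method <- match.arg(method)
  if (!is.null(k) && method != "who")
    stop("`k` applies to the \"who\" method only", call. = FALSE)
  if (!is.null(tkpy) && method != "ai")
    stop("`tkpy` applies to the \"ai\" method only", call. = FALSE)
  if (method == "who" && is.null(k)) k <- 10       # mgcv-style default
  if (method == "ai" && is.null(tkpy)) tkpy <- 1 / 7  # reference default
  if (start_year > train_end)
    stop("`start_year` must not exceed `train_end`", call. = FALSE)

  tr <- series[series$iso_year >= start_year & series$iso_year <= train_end, ,
               drop = FALSE]
  got <- unique(tr$iso_year)
  need <- seq.int(start_year, train_end)
  if (!all(need %in% got))
    stop("series does not cover training years ",
         paste(setdiff(need, got), collapse = ", "), call. = FALSE)
  yearly_totals(tr, need)  # errors if any year is partially covered

  n_years <- train_end - start_year + 1L
  trend_basis <- NULL
  trend_type <- NULL
  engine <- switch(method,
    average = pgam(tr$deaths,
                   smooths = list(cyclic_cubic_basis(tr$w, k = seasonal_k)),
                   family = "nb"),
    linear = pgam(tr$deaths, parametric = cbind(t = tr$t_days),
                  smooths = list(cyclic_cubic_basis(tr$w, k = seasonal_k)),
                  family = "nb"),
    who = pgam(tr$deaths,
               smooths = list(tprs_basis(tr$t_days, k = k),
                              cyclic_cubic_basis(tr$w, k = seasonal_k)),
               family = "nb"),
    ai = {
      trend_df <- max(1L, floor(tkpy * n_years))
      # decade-scale, centred time keeps the quasi-Poisson IRLS well
      # conditioned; predictions are invariant to this affine rescaling
      t_sc <- (tr$t_days - mean(tr$t_days)) / 3650
      if (n_years < 7 || trend_df < 2L) {
        trend_type <- "linear"
        X <- cbind(t = t_sc, harmonic_design(tr$w))
      } else {
        trend_type <- "natural-cubic"
        trend_basis <- natural_cubic_basis(tr$t_days, n_knots = trend_df - 1L,
                                           range = range(tr$t_days))
        X <- cbind(trend_basis$values, harmonic_design(tr$w))
      }
      pgam(tr$deaths, parametric = X, family = "quasipoisson")
    })

  structure(list(
    method = method, start_year = start_year, train_end = train_end,
    k = k, tkpy = tkpy, seasonal_k = seasonal_k,
    trend_type = trend_type, trend_basis = trend_basis,
    engine = engine, converged = engine$converged,
    training = tr), class = "baseline_fit")
}

# design pieces for predict/fitted on an arbitrary grid
baseline_design <- function(object, grid) {
  switch(object$method,
    average = list(parametric = NULL, smooth_x = list(grid$w)),
    linear = list(parametric = cbind(t = grid$t_days),
                  smooth_x = list(grid$w)),
    who = list(parametric = NULL, smooth_x = list(grid$t_days, grid$w)),
    ai = {
      trend <- if (object$trend_type == "linear")
        cbind(t = (grid$t_days - mean(object$training$t_days)) / 3650)
      else eval_basis(object$trend_basis, grid$t_days)
      list(parametric = cbind(trend, harmonic_design(grid$w)),
           smooth_x = list())
    })
}

#' Predict baseline mortality
#'
#' Predicts expected weekly deaths on an ISO-week grid and, by default,
#' sums them to yearly totals.  53-week target years automatically sum 53
#' weekly predictions.
#'
#' @param object a [baseline_fit()].
#' @param years integer vector of target years (default 2020:2023), used
#'   when `newdata` is not given.
#' @param newdata optionally, explicit [week_grid()] rows to predict on.
#' @param type `"yearly"` (data frame `year`, `predicted`), `"weekly"`
#'   (grid plus an `expected` column) or `"terms"` (per-block linear
#'   predictor contributions, useful for inspecting the extrapolated
#'   trend).
#' @param ... unused.
#' @export
predict.baseline_fit <- function(object, years = 2020:2023, newdata = NULL,
                                 type = c("yearly", "weekly", "terms"), ...) {
  type <- match.arg(type)
  grid <- if (!is.null(newdata)) newdata else
    week_grid(min(years), max(years))
  grid <- grid[if (is.null(newdata)) grid$iso_year %in% years else TRUE, ,
               drop = FALSE]
  d <- baseline_design(object, grid)
  if (type == "terms")
    return(predict(object$engine, parametric = d$parametric,
                   smooth_x = d$smooth_x, type = "terms"))
  mu <- predict(object$engine, parametric = d$parametric,
                smooth_x = d$smooth_x, type = "response")
  if (type == "weekly") {
    out <- as.data.frame(grid)
    out$expected <- mu
    return(out)
  }
  agg <- tapply(mu, grid$iso_year, sum)
  data.frame(year = as.integer(names(agg)), predicted = as.numeric(agg),
             row.names = NULL)
}

#' @export
fitted.baseline_fit <- function(object, ...) {
  d <- baseline_design(object, object$training)
  predict(object$engine, parametric = d$parametric, smooth_x = d$smooth_x,
          type = "response")
}

#' @export
residuals.baseline_fit <- function(object, type = "deviance", ...) {
  stats::residuals(object$engine$fit, type = type)
}

#' @export
coef.baseline_fit <- function(object, ...) coef(object$engine)

#' @export
print.baseline_fit <- function(x, ...) {
  hp <- switch(x$method, who = sprintf(", k = %d", x$k),
               ai = sprintf(", tkpy = %.4g (%s trend)", x$tkpy, x$trend_type),
               "")
  cat(sprintf("baseline mortality fit: method \"%s\"%s, trained %d-%d\n",
              x$method, hp, x$start_year, x$train_end))
  if (!x$converged) cat("  WARNING: underlying fit did not converge\n")
  invisible(x)
}

#' @export
summary.baseline_fit <- function(object, ...) {
  print(object)
  print(object$engine)
  invisible(object)
}

#' @export
plot.baseline_fit <- function(x, years = 2020:2023, ...) {
  tr <- x$training
  pw <- predict(x, years = years, type = "weekly")
  xr <- range(tr$t_days, pw$t_days)
  plot(tr$t_days, tr$deaths, pch = 16, cex = 0.4, col = "grey40",
       xlim = xr, ylim = range(tr$deaths, pw$expected),
       xlab = "days since 1970-01-01", ylab = "weekly deaths", ...)
  lines(tr$t_days, fitted(x), col = "steelblue", lwd = 1.5)
  lines(pw$t_days, pw$expected, col = "firebrick", lwd = 1.5)
  legend("topleft", bty = "n", lwd = 1.5, col = c("steelblue", "firebrick"),
         legend = c("fitted (training)", "predicted baseline"))
  invisible(x)
}

#' Fit a baseline method and return actual and predicted yearly totals
#'
#' Convenience wrapper: fits [baseline_fit()] on the training window and
#' returns, for each target year, the predicted yearly total and (when the
#' series covers the target years, as a simulated series does) the actual
#' total.
#'
#' @inheritParams baseline_fit
#' @param target_years years to predict (default 2020:2023).
#' @return data frame with columns `year`, `actual` (NA if the series does
#'   not cover the year) and `predicted`, with the fit's convergence flag
#'   in attribute `converged`.
#' @export
fit_and_predict <- function(series, method, start_year = 2000, k = NULL,
                            tkpy = NULL, target_years = 2020:2023,
                            train_end = 2019, seasonal_k = 10) {
  fit <- baseline_fit(series, method, start_year = start_year, k = k,
                      tkpy = tkpy, train_end = train_end,
                      seasonal_k = seasonal_k)
  pred <- predict(fit, years = target_years)
  covered <- vapply(target_years, function(y)
    y %in% series$iso_year &&
      length(series$iso_week[series$iso_year == y]) == weeks_in_iso_year(y),
    logical(1))
  actual <- rep(NA_real_, length(target_years))
  if (any(covered))
    actual[covered] <- yearly_totals(series, target_years[covered])$deaths
  out <- data.frame(year = target_years, actual = actual,
                    predicted = pred$predicted[match(target_years, pred$year)])
  attr(out, "converged") <- fit$converged
  out
}

#' The investigated method/hyperparameter grid
#'
#' All method parametrizations compared in the simulation study: average
#' with starting years 2000, 2005, 2010, 2015 and 2019; linear with
#' starting years 2000, 2005, 2010 and 2015; who with those four starting
#' years crossed with trend basis dimension k in {3, 5, 10, 15, 20}; ai
#' with the same starting years crossed with tkpy in
#' {1/4, 1/5, 1/7, 1/9, 1/12}.
#'
#' @return data frame with columns `method`, `start_year`, `k`, `tkpy`.
#' @export
method_grid <- function() {
  starts <- c(2000L, 2005L, 2010L, 2015L)
  rbind(
    data.frame(method = "average", start_year = c(starts, 2019L),
               k = NA_integer_, tkpy = NA_real_),
    data.frame(method = "linear", start_year = starts,
               k = NA_integer_, tkpy = NA_real_),
    expand.grid(method = "who", start_year = starts,
                k = c(3L, 5L, 10L, 15L, 20L), tkpy = NA_real_,
                stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)[, c("method", "start_year", "k", "tkpy")],
    expand.grid(method = "ai", start_year = starts, k = NA_integer_,
                tkpy = c(1 / 4, 1 / 5, 1 / 7, 1 / 9, 1 / 12),
                stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)[, c("method", "start_year", "k", "tkpy")])
}
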