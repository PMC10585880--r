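# Synthetic weekly death-count generator.

#' Draw the random seasonal peaks for a simulated series
#'
#' For each ISO year covered by the grid and each season independently, one
#' peak occurs with the season's yearly probability.  The peak location is
#' continuous-uniform over the season's week window (in days on the
#' timeline, so tails cross year boundaries naturally); height and width
#' are uniform within the law's bounds.
#'
#' Uses the current R random number stream; seed upstream (or via
#' [simulate_mortality()]) for reproducibility.
#'
#' @param grid a [week_grid()].
#' @param params a [scenario_params()] object.
#' @return a data frame of class `peak_set` with columns `season`, `year`,
#'   `location` (days since 1970-01-01 of the peak mode), `width` (Cauchy
#'   scale, days) and `height` (log scale).
#' @export
sample_peaks <- function(grid, params) {
  stopifnot(nrow(grid) > 0)
  params <- as_scenario_params(params)
  out <- vector("list", 0L)
  for (y in unique(grid$iso_year)) {
    week1_t <- grid$t_days[grid$iso_year == y & grid$iso_week == 1L]
    for (season in c("winter", "summer")) {
      law <- params[[season]]
      if (stats::runif(1) < law$probability) {
        # week j of the year sits at week1_t + 7*(j-1) days; the location is
        # uniform over [week_lo, week_hi] on that continuous week scale
        loc <- week1_t + 7 * stats::runif(1, law$week_lo - 1, law$week_hi - 1)
        out[[length(out) + 1L]] <- data.frame(
          season = season, year = y, location = loc,
          width = stats::runif(1, law$width_min, law$width_max),
          height = stats::runif(1, law$height_min, law$height_max))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(season = character(), year = integer(), location = numeric(),
               width = numeric(), height = numeric())
  class(res) <- c("peak_set", "data.frame")
  res
}

#' Expected weekly deaths of a scenario
#'
#' Evaluates the mean curve
#' `log(mu_t) = beta0 + beta1 t + beta2 t^2 + A cos(2 pi w + phi) + peaks`,
#' where each peak contributes a Cauchy-shaped bump on the day timeline,
#' `height * width^2 / ((t - location)^2 + width^2)`: `width` is the Cauchy
#' scale (half width at half maximum) in days, and the kernel is scaled so
#' the bump equals `height` at its mode.  Peak terms are evaluated over
#' the whole timeline, so tails cross year boundaries.
#'
#' @param grid a [week_grid()].
#' @param params a [scenario_params()] object.
#' @param peaks a `peak_set` as returned by [sample_peaks()]; defaults to no
#'   peaks.
#' @return numeric vector of expected deaths per grid row (strictly
#'   positive).
#' @export
#' @examples
#' g <- week_grid(2000, 2001)
#' mu <- mean_curve(g, scenario_params("constant"))
mean_curve <- function(grid, params, peaks = NULL) {
  params <- as_scenario_params(params)
  t <- grid$t_days
  log_mu <- params$beta0 + params$beta1 * t + params$beta2 * t^2 +
    params$A * cos(2 * pi * grid$w + params$phi)
  if (!is.null(peaks) && nrow(peaks) > 0) {
    for (i in seq_len(nrow(peaks))) {
      gamma <- peaks$width[i]
      log_mu <- log_mu +
        peaks$height[i] * gamma^2 / ((t - peaks$location[i])^2 + gamma^2)
    }
  }
  mu <- exp(log_mu)
  if (!all(is.finite(mu)))
    stop("non-finite expected deaths; check scenario parameters",
         call. = FALSE)
  mu
}

#' Simulate a weekly death-count series
#'
#' Draws one synthetic weekly all-cause mortality series: seasonal peaks
#' are sampled by [sample_peaks()], the mean curve is computed by
#' [mean_curve()], and counts are drawn independently as negative binomial
#' with mean `mu_t` and size `params$size` (variance `mu + mu^2/size`).
#'
#' @param scenario a scenario name (see [scenario_params()]) or a
#'   `scenario_params` object.  Default: the base case.
#' @param start_year,end_year ISO years covered (default 2000-2023).
#' @param seed optional integer; if given, `set.seed(seed)` is called first
#'   so the series is fully reproducible.
#' @param grid optionally, a pre-built [week_grid()] (overrides the year
#'   arguments).
#' @return a data frame of class `weekly_series`: the grid columns plus
#'   `mu` (true expected deaths) and `deaths` (simulated counts).  The
#'   realised peaks and the generating parameters are attached as
#'   attributes `peaks` and `params` (ground truth for downstream checks).
#' @export
#' @examples
#' s <- simulate_mortality("linear", seed = 42)
#' head(s)
#' attr(s, "peaks")
simulate_mortality <- function(scenario = base_case_params(),
                               start_year = 2000, end_year = 2023,
                               seed = NULL, grid = NULL) {
  params <- as_scenario_params(scenario)
  if (is.null(grid)) grid <- week_grid(start_year, end_year)
  if (!is.null(seed)) set.seed(seed)
  peaks <- sample_peaks(grid, params)
  mu <- mean_curve(grid, params, peaks)
  out <- as.data.frame(grid)
  out$mu <- mu
  out$deaths <- stats::rnbinom(nrow(out), mu = mu, size = params$size)
  attr(out, "peaks") <- peaks
  attr(out, "params") <- params
  class(out) <- c("weekly_series", "data.frame")
  out
}
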