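# Generative scenario parameters for the synthetic weekly mortality model.
#
# Weekly death counts are simulated as D_t ~ NegBin(mu_t, size) with
#   log(mu_t) = beta0 + beta1 * t + beta2 * t^2 + A * cos(2*pi*w + phi)
#               + seasonal peak terms,
# where t is days since 1970-01-01 and w the scaled week of year.  Winter
# (flu-season) and summer (heat-wave) peaks occur at most once per season
# and year, with Cauchy-shaped profiles on the day timeline.

#' Describe the law of a seasonal mortality peak
#'
#' In each year, with probability `probability`, one peak is added to the
#' log mean curve.  Its maximum height (log scale), width (Cauchy scale,
#' i.e. half width at half maximum, in days) and location
#' (continuous-uniform over a window of ISO weeks) are drawn uniformly
#' from the stated ranges.
#'
#' @param probability yearly occurrence probability in `[0, 1]`.
#' @param height length-2 numeric, min and max peak height on the log scale.
#' @param width length-2 numeric, min and max Cauchy scale of the peak, in
#'   days.
#' @param weeks length-2 integer, first and last ISO week of the location
#'   window.
#' @return an object of class `peak_law`.
#' @export
#' @examples
#' peak_law(0.45, height = c(0.11, 0.33), width = c(8.41, 35.36),
#'          weeks = c(1, 11))
peak_law <- function(probability, height, width, weeks) {
  stopifnot(length(probability) == 1L, probability >= 0, probability <= 1,
            length(height) == 2L, height[1] <= height[2],
            length(width) == 2L, width[1] <= width[2], width[1] > 0,
            length(weeks) == 2L, weeks[1] <= weeks[2])
  structure(list(probability = probability,
                 height_min = height[1], height_max = height[2],
                 width_min = width[1], width_max = width[2],
                 week_lo = as.integer(weeks[1]), week_hi = as.integer(weeks[2])),
            class = "peak_law")
}

#' @export
print.peak_law <- function(x, ...) {
  cat(sprintf(
    "peak law: p = %.2f/year, height %.2f-%.2f (log), scale %.2f-%.2f days, weeks %d-%d\n",
    x$probability, x$height_min, x$height_max, x$width_min, x$width_max,
    x$week_lo, x$week_hi))
  invisible(x)
}

#' Scenario parameters of the synthetic mortality model
#'
#' `base_case_params()` returns the calibrated German-like parameter set:
#' a quadratic log-scale trend (`beta0 = 10.11`, `beta1 = -7.36e-5`,
#' `beta2 = 3.04e-9` on days since 1970), one seasonal harmonic
#' (`A = 0.07`, `phi = -0.61`), negative-binomial size 1000, winter peaks
#' (probability 0.45/year, heights 0.11-0.33, widths 8.41-35.36, weeks
#' 1-11) and summer peaks (probability 0.40/year, heights 0.10-0.24,
#' widths 0.86-9.24, weeks 26-37).
#'
#' `scenario_params(name)` returns the base case with the long-term trend
#' replaced:
#' \describe{
#'   \item{`"quadratic"`}{the base case itself;}
#'   \item{`"linear"`}{`beta2 = 0`;}
#'   \item{`"constant"`}{`beta1 = beta2 = 0`;}
#'   \item{`"nonmonotone"`}{`beta0 = 10`, `beta1 = 9.5e-5`, `beta2 = -3e-9`.}
#' }
#'
#' @param name one of `"constant"`, `"linear"`, `"quadratic"`,
#'   `"nonmonotone"`.
#' @return an object of class `scenario_params`: a list with elements
#'   `beta0`, `beta1`, `beta2`, `A`, `phi`, `size`, `winter`, `summer` and
#'   `name`.
#' @export
#' @examples
#' base_case_params()$beta0      # 10.11
#' scenario_params("constant")   # beta1 = beta2 = 0
base_case_params <- function() {
  structure(list(
    beta0 = 10.11, beta1 = -7.36e-5, beta2 = 3.04e-9,
    A = 0.07, phi = -0.61, size = 1000,
    winter = peak_law(0.45, height = c(0.11, 0.33),
                      width = c(8.41, 35.36), weeks = c(1L, 11L)),
    summer = peak_law(0.40, height = c(0.10, 0.24),
                      width = c(0.86, 9.24), weeks = c(26L, 37L)),
    name = "quadratic"), class = "scenario_params")
}

#' @rdname base_case_params
#' @export
scenario_params <- function(name = c("quadratic", "linear", "constant",
                                     "nonmonotone")) {
  name <- match.arg(name)
  p <- base_case_params()
  p$name <- name
  switch(name,
         quadratic = {},
         linear = { p$beta2 <- 0 },
         constant = { p$beta1 <- 0; p$beta2 <- 0 },
         nonmonotone = { p$beta0 <- 10; p$beta1 <- 9.5e-5; p$beta2 <- -3e-9 })
  p
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf("scenario \"%s\": log(mu) = %.4g %+.4g t %+.4g t^2 + %.2f cos(2 pi w %+.2f)\n",
              x$name, x$beta0, x$beta1, x$beta2, x$A, x$phi))
  cat(sprintf("negative-binomial size: %g\n", x$size))
  cat("winter "); print(x$winter)
  cat("summer "); print(x$summer)
  invisible(x)
}

as_scenario_params <- function(scenario) {
  if (inherits(scenario, "scenario_params")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1L)
    return(scenario_params(scenario))
  stop("`scenario` must be a scenario name or a scenario_params object",
       call. = FALSE)
}
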