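# Reporting helpers: fixture generation, summary tables and figures.

#' Write a deterministic synthetic weekly series fixture
#'
#' One base-case simulated series 2000-2023 in the weekly-series CSV
#' layout (`iso_year,iso_week,deaths`), byte-identical for a given seed.
#' Used by tests and examples in place of any real-data download.
#'
#' @param path output CSV path.
#' @param seed integer seed.
#' @return the path, invisibly.
#' @export
make_fixture <- function(path, seed = 1) {
  s <- simulate_mortality(base_case_params(), seed = seed)
  write_weekly_series(s, path)
}

#' Tabulate and plot a method-comparison study
#'
#' Produces the study's headline outputs: a best-parametrization table
#' (mean +/- SD of each metric, methods in the order AI, Average, Linear,
#' WHO), and optionally two figures -- a per-parametrization metric panel
#' (log MSE, MAPE, bias) and a mean-MSE-versus-starting-year line chart on
#' a log scale.
#'
#' @param study a [run_study()] result or its summary data frame.
#' @param plots draw the figures on the current graphics device?
#' @return invisibly, a list with `table` (formatted best-parametrization
#'   table) and `summary` (the full per-configuration summary).
#' @export
render_report <- function(study, plots = TRUE) {
  s <- if (inherits(study, "mortality_study")) summary(study) else study
  if (!is.data.frame(s) || nrow(s) == 0) {
    warning("no study records; empty report", call. = FALSE)
    return(invisible(list(table = data.frame(), summary = data.frame())))
  }
  best <- best_parametrization(s)
  ord <- match(c("ai", "average", "linear", "who"), best$method)
  best <- best[ord[!is.na(ord)], ]
  pm <- function(m, sd) ifelse(is.na(sd), sprintf("%.1f", m),
                               sprintf("%.1f ± %.1f", m, sd))
  tab <- data.frame(
    method = c(ai = "AI", average = "Average", linear = "Linear",
               who = "WHO")[best$method],
    config = best$config,
    mse = pm(best$mean_mse, best$sd_mse),
    mape = pm(best$mean_mape, best$sd_mape),
    bias = pm(best$mean_bias, best$sd_bias),
    row.names = NULL)
  if (plots) {
    if (any(s$mean_mse <= 0))
      stop("non-positive mean MSE; cannot draw log-scale panels",
           call. = FALSE)
    op <- graphics::par(mfrow = c(1, 3), mar = c(9, 4, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
    cols <- c(average = "grey40", linear = "forestgreen",
              who = "firebrick", ai = "steelblue")
    for (metric in c("mean_mse", "mean_mape", "mean_bias")) {
      vals <- if (metric == "mean_mse") log(s[[metric]]) else s[[metric]]
      graphics::plot(seq_len(nrow(s)), vals, pch = 16,
                     col = cols[s$method], xaxt = "n", xlab = "",
                     ylab = c(mean_mse = "log mean MSE",
                              mean_mape = "mean MAPE (%)",
                              mean_bias = "mean bias (thousands)")[metric],
                     main = c(mean_mse = "MSE", mean_mape = "MAPE",
                              mean_bias = "Bias")[metric])
      graphics::axis(1, at = seq_len(nrow(s)), labels = s$config, las = 2,
                     cex.axis = 0.6)
    }
    plot_mse_by_start(s)
  }
  invisible(list(table = tab, summary = s))
}

# Fig-5-style chart: mean MSE vs starting year, log scale, one line per
# method (at each method's modal hyperparameter if several are present).
plot_mse_by_start <- function(s) {
  cols <- c(average = "grey40", linear = "forestgreen",
            who = "firebrick", ai = "steelblue")
  graphics::par(mfrow = c(1, 1), mar = c(4, 4, 2, 1))
  graphics::plot(range(s$start_year), range(s$mean_mse), type = "n",
                 log = "y", xlab = "starting year",
                 ylab = "mean MSE (thousands^2, log scale)",
                 main = "mean MSE by starting year")
  for (meth in unique(s$method)) {
    d <- s[s$method == meth, ]
    # one line per hyperparameter value
    key <- if (meth == "who") d$k else if (meth == "ai") d$tkpy else
      rep(1, nrow(d))
    for (kk in unique(key)) {
      dd <- d[key == kk, ]
      dd <- dd[order(dd$start_year), ]
      graphics::lines(dd$start_year, dd$mean_mse, col = cols[meth],
                      type = "b", pch = 16, cex = 0.7)
    }
  }
  graphics::legend("topleft", bty = "n", col = cols, pch = 16,
                   legend = names(cols))
}

#' @export
plot.mortality_study <- function(x, ...) {
  plot_mse_by_start(summary(x))
  invisible(x)
}
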