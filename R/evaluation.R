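# Monte-Carlo comparison of the baseline predictors.
#
# One replication = simulate a series (2000-2023), fit every investigated
# method parametrization on its training window, predict the 2020-2023
# yearly totals and score them against the simulated truth.  Errors of
# yearly totals are expressed in thousands of deaths, so a typical
# German-scale yearly total (~1e6) is ~1000 on the metric scale.

config_label <- function(method, start_year, k, tkpy) {
  paste0(method, "/", start_year,
         ifelse(!is.na(k), paste0("/k=", k), ""),
         ifelse(!is.na(tkpy), paste0("/tkpy=1/", round(1 / tkpy)), ""))
}

#' Error metrics of predicted yearly totals
#'
#' For actual totals `M_y` and predictions `Mhat_y` over the target years:
#' `MSE = mean((M_y - Mhat_y)^2)` and `Bias = mean(M_y - Mhat_y)`, both
#' with totals expressed in thousands of deaths, and
#' `MAPE = mean(|M_y - Mhat_y| / M_y)` in percent.
#'
#' @param actual,predicted numeric vectors of yearly totals in deaths (same
#'   length; or data frames with columns `year` and `deaths`/`predicted`).
#' @return named numeric vector `c(mse, mape, bias)`.
#' @export
#' @examples
#' prediction_metrics(rep(1e6, 4), rep(99e4, 4))  # mse 100, mape 1, bias 10
prediction_metrics <- function(actual, predicted) {
  if (is.data.frame(actual)) actual <- actual$deaths
  if (is.data.frame(predicted)) predicted <- predicted$predicted
  stopifnot(length(actual) == length(predicted), length(actual) >= 1)
  if (any(!is.finite(actual)) || any(!is.finite(predicted)))
    stop("totals must be finite", call. = FALSE)
  if (any(actual == 0))
    stop("MAPE is undefined when an actual yearly total is 0", call. = FALSE)
  d <- (actual - predicted) / 1000
  c(mse = mean(d^2),
    mape = 100 * mean(abs(actual - predicted) / actual),
    bias = mean(d))
}

#' Run the Monte-Carlo method-comparison study
#'
#' For each replication `r`, one series is simulated from the scenario
#' (with seed `base_seed + r`, so results are reproducible and adding
#' configurations never changes existing ones) and every configuration is
#' fitted and scored on that same dataset.
#'
#' @param scenario scenario name or [scenario_params()] object.
#' @param configs data frame of configurations (columns `method`,
#'   `start_year`, `k`, `tkpy`), e.g. [method_grid()] or a subset.
#' @param n_reps number of replications (>= 1).
#' @param base_seed integer; replication `r` uses seed `base_seed + r`.
#' @param target_years years scored (default 2020:2023).
#' @param sim_start first simulated year (default 2000).
#' @param verbose print a progress line per replication?
#' @return an object of class `mortality_study`: list with `metrics` (one
#'   row per replication x configuration: `rep`, `config`, `method`,
#'   `start_year`, `k`, `tkpy`, `mse`, `mape`, `bias`, `converged`),
#'   `scenario`, `n_reps`, `base_seed`.  If any configuration fails to fit
#'   on more than 5\% of replications the study aborts with a diagnostic
#'   listing the failing replications.
#' @seealso [summary.mortality_study()], [best_parametrization()],
#'   [compare_paired()]
#' @export
run_study <- function(scenario, configs = method_grid(), n_reps,
                      base_seed = 1, target_years = 2020:2023,
                      sim_start = 2000, verbose = FALSE) {
  stopifnot(n_reps >= 1)
  params <- as_scenario_params(scenario)
  configs <- as.data.frame(configs)
  stopifnot(all(c("method", "start_year") %in% names(configs)))
  if (is.null(configs$k)) configs$k <- NA_integer_
  if (is.null(configs$tkpy)) configs$tkpy <- NA_real_
  grid <- week_grid(sim_start, max(target_years))

  rows <- vector("list", n_reps * nrow(configs))
  fails <- list()
  warn_log <- list()
  for (r in seq_len(n_reps)) {
    set.seed(base_seed + r)
    s <- simulate_mortality(params, grid = grid)
    actual <- yearly_totals(s, target_years)$deaths
    for (j in seq_len(nrow(configs))) {
      cf <- configs[j, ]
      lab <- config_label(cf$method, cf$start_year, cf$k, cf$tkpy)
      m <- tryCatch({
        fp <- withCallingHandlers(
          fit_and_predict(s, cf$method, start_year = cf$start_year,
                          k = if (is.na(cf$k)) NULL else cf$k,
                          tkpy = if (is.na(cf$tkpy)) NULL else cf$tkpy,
                          target_years = target_years),
          warning = function(w) {
            # collect per-fit convergence chatter; summarised once at the end
            warn_log[[length(warn_log) + 1L]] <<-
              list(config = lab, rep = r, message = conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        c(prediction_metrics(actual, fp$predicted),
          converged = as.numeric(attr(fp, "converged")))
      }, error = function(e) {
        fails[[length(fails) + 1L]] <<- list(config = lab, rep = r,
                                             message = conditionMessage(e))
        c(mse = NA_real_, mape = NA_real_, bias = NA_real_,
          converged = NA_real_)
      })
      rows[[(r - 1L) * nrow(configs) + j]] <- data.frame(
        rep = r, config = lab, method = cf$method,
        start_year = cf$start_year, k = cf$k, tkpy = cf$tkpy,
        mse = m[["mse"]], mape = m[["mape"]], bias = m[["bias"]],
        converged = as.logical(m[["converged"]]))
    }
    if (verbose) message("replication ", r, "/", n_reps, " done")
  }
  metrics <- do.call(rbind, rows)

  if (length(warn_log)) {
    wtab <- sort(table(vapply(warn_log, `[[`, character(1), "config")),
                 decreasing = TRUE)
    warning(length(warn_log), " fit warning(s) across ",
            sum(!metrics$converged, na.rm = TRUE),
            " non-converged fit(s) of ", nrow(metrics),
            "; most affected: ",
            paste(utils::head(names(wtab), 3), "(", utils::head(wtab, 3), ")",
                  collapse = ", "), call. = FALSE)
  }

  if (length(fails)) {
    ftab <- table(vapply(fails, `[[`, character(1), "config"))
    bad <- names(ftab)[ftab > 0.05 * n_reps]
    if (length(bad)) {
      detail <- vapply(fails, function(f)
        sprintf("%s (rep %d): %s", f$config, f$rep, f$message), character(1))
      stop("configuration(s) failed on more than 5% of replications: ",
           paste(bad, collapse = ", "), "\n",
           paste(utils::head(detail, 20), collapse = "\n"), call. = FALSE)
    }
  }
  structure(list(metrics = metrics, scenario = params$name, n_reps = n_reps,
                 base_seed = base_seed, target_years = target_years),
            class = "mortality_study")
}

#' Aggregate a study to per-configuration means and SDs
#'
#' @param object a [run_study()] result.
#' @param ... unused.
#' @return data frame with one row per configuration: mean and sample SD
#'   (denominator `n - 1`; `NA` when a single replication) of each metric,
#'   and the replication count used.
#' @export
summary.mortality_study <- function(object, ...) {
  m <- object$metrics
  agg <- do.call(rbind, lapply(split(m, m$config), function(d) {
    ok <- stats::complete.cases(d[, c("mse", "mape", "bias")])
    dd <- d[ok, ]
    data.frame(config = d$config[1], method = d$method[1],
               start_year = d$start_year[1], k = d$k[1], tkpy = d$tkpy[1],
               mean_mse = mean(dd$mse),
               sd_mse = if (nrow(dd) > 1) stats::sd(dd$mse) else NA_real_,
               mean_mape = mean(dd$mape),
               sd_mape = if (nrow(dd) > 1) stats::sd(dd$mape) else NA_real_,
               mean_bias = mean(dd$bias),
               sd_bias = if (nrow(dd) > 1) stats::sd(dd$bias) else NA_real_,
               n_reps = nrow(dd))
  }))
  rownames(agg) <- NULL
  agg[order(agg$method, agg$start_year, agg$k, agg$tkpy), ]
}

#' @export
print.mortality_study <- function(x, ...) {
  cat(sprintf("Monte-Carlo baseline-mortality study: scenario \"%s\", %d replication(s), %d configuration(s)\n",
              x$scenario, x$n_reps, length(unique(x$metrics$config))))
  s <- summary(x)
  cat("best parametrization per method (by mean MSE, thousands^2):\n")
  print(best_parametrization(s)[, c("config", "mean_mse", "sd_mse",
                                    "mean_mape", "mean_bias")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Best parametrization of each method
#'
#' Selects, for each method, the configuration with the lowest mean MSE.
#' Ties are broken deterministically: earlier starting year, then smaller
#' `k`, then smaller `tkpy` (i.e. the more rigid trend), with a message
#' when a tie occurs.
#'
#' @param x a `mortality_study` or its [summary.mortality_study()] data
#'   frame.
#' @return the selected summary rows, one per method.
#' @export
best_parametrization <- function(x) {
  s <- if (inherits(x, "mortality_study")) summary(x) else x
  if (!is.data.frame(s) || nrow(s) == 0)
    stop("no study records to select from", call. = FALSE)
  out <- do.call(rbind, lapply(split(s, s$method), function(d) {
    best <- d[d$mean_mse == min(d$mean_mse), , drop = FALSE]
    if (nrow(best) > 1) {
      message("tie on mean MSE for method ", d$method[1],
              "; choosing earliest start year, then smallest k / tkpy")
      o <- order(best$start_year, best$k, best$tkpy, na.last = TRUE)
      best <- best[o, , drop = FALSE]
    }
    best[1, , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Paired comparison of two configurations
#'
#' Because every configuration is evaluated on the same simulated dataset
#' within a replication, per-replication error differences can be compared
#' directly, not just the averages.
#'
#' @param study a [run_study()] result containing both configurations.
#' @param config_a,config_b configuration labels as in
#'   `study$metrics$config` (e.g. `"linear/2000"`, `"who/2000/k=3"`).
#' @param metric which metric to compare (default `"mse"`).
#' @return list with the per-replication differences (`a - b`), their
#'   `mean` and `sd`, and `frac_a_better`, the fraction of replications
#'   where `a` has the strictly smaller error (ties counted half).
#' @export
compare_paired <- function(study, config_a, config_b, metric = "mse") {
  stopifnot(inherits(study, "mortality_study"),
            metric %in% c("mse", "mape", "bias"))
  m <- study$metrics
  a <- m[m$config == config_a, ]
  b <- m[m$config == config_b, ]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("configuration not present in the study", call. = FALSE)
  if (!identical(a$rep, b$rep))
    stop("configurations were not evaluated on the same replications",
         call. = FALSE)
  d <- a[[metric]] - b[[metric]]
  list(config_a = config_a, config_b = config_b, metric = metric,
       differences = d, mean = mean(d),
       sd = if (length(d) > 1) stats::sd(d) else NA_real_,
       frac_a_better = mean(d < 0) + 0.5 * mean(d == 0))
}
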