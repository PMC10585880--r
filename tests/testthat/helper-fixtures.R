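# Shared fixtures: generated in code, cached for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a scenario with peaks switched off (and optionally no seasonality),
# useful wherever the deterministic part of the mean curve is the target
peakless_params <- function(name = "quadratic", A = NULL) {
  p <- scenario_params(name)
  p$winter$probability <- 0
  p$summer$probability <- 0
  if (!is.null(A)) p$A <- A
  p
}

# one simulated base-case series shared by read-only tests
base_series <- function() cached("base_series",
                                 simulate_mortality(seed = 101))

grid_2000_2023 <- function() cached("grid_2000_2023", week_grid(2000, 2023))
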