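# Shared fixtures: the calibrated baseline parameter set, the working
# life-history preset, and small raster builders. Everything is built in
# code; no fixture files.

baseline_params <- function(...) model_parameters(...)

lh_working <- function(...) life_history_parameters(...)

# Random-but-valid parameter sets for property tests (seeded by caller).
random_params <- function() {
  model_parameters(
    r = runif(1, 0.1, 2),
    beta = runif(1, 0.05, 1),
    gamma = runif(1, 0.05, 1),
    alpha = runif(1, 0, 0.5),
    mu = runif(1, 0.01, 0.3),
    mu_i = runif(1, 0, 0.2),
    N = runif(1, 10, 500)
  )
}

random_state <- function() {
  c(S = runif(1, 0, 50), R = runif(1, 0, 50), M = runif(1, 0, 50))
}

# A small raster with the given values (north-first rows).
tiny_raster <- function(values, nrow = 2, xll = 0, yll = 0, cellsize = 0.5) {
  if (!is.matrix(values)) values <- matrix(values, nrow = nrow)
  raster_grid(values, xll, yll, cellsize)
}

# 12 co-registered monthly rasters with per-month constant values.
constant_months <- function(month_values, nrow = 2, ncol = 2) {
  lapply(month_values, function(v) {
    tiny_raster(matrix(v, nrow, ncol), nrow = nrow)
  })
}
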