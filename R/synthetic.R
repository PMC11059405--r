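# Seeded synthetic climate fields and resistance observation points. The
# generator emulates the statistical structure the pipeline assumes —
# seasonally varying temperature and rainfall over a georeferenced grid,
# and point sets with known placement relative to risk classes — so every
# stage can be tested end-to-end with no external data.

#' Generate synthetic monthly climate rasters
#'
#' Twelve months of temperature and rainfall over an Africa-like toy
#' extent. Temperature is a latitudinal gradient around `T_mean` plus a
#' sinusoidal seasonal cycle of amplitude `T_amplitude` and truncated
#' Gaussian noise, clamped to \[0, 45\] degC. Rainfall is a seasonal bump
#' peaking at `rain_peak` in month `wet_season_center` (for the wettest
#' latitude band), modulated across latitude, plus noise, floored at 0.
#' With `noise_sd = c(0, 0)` the wettest pixel-month receives exactly
#' `rain_peak` mm. All randomness sits behind the single `seed`.
#'
#' @param rows,cols Grid shape (default 40 x 40).
#' @param T_mean Mean temperature (degC) of the central latitude band.
#' @param T_amplitude Seasonal temperature amplitude (degC).
#' @param T_gradient Temperature change per degree of latitude away from
#'   the grid's central latitude (degC/deg, default -0.15).
#' @param rain_peak Peak monthly rainfall (mm).
#' @param wet_season_center Month index (1-12) of the rainfall peak.
#' @param noise_sd Length-2 numeric: Gaussian noise SD for temperature
#'   (degC) and rainfall (mm).
#' @param cellsize Cell size (degrees, default 0.5).
#' @param origin Lower-left corner `c(x, y)` (default `c(-20, -35)`).
#' @param seed Integer seed (required).
#' @return A list with elements `temperature` and `rainfall`, each a list
#'   of 12 `irmap_raster` grids, plus the echoed `spec`.
#' @examples
#' clim <- synth_climate(rows = 10, cols = 10, seed = 1)
#' clim$temperature[[1]]
#' @export
synth_climate <- function(rows = 40, cols = 40, T_mean = 25, T_amplitude = 4,
                          T_gradient = -0.15, rain_peak = 25,
                          wet_season_center = 7, noise_sd = c(0.5, 2),
                          cellsize = 0.5, origin = c(-20, -35), seed) {
  if (rows < 1 || cols < 1) abort("grid must be at least 1 x 1")
  if (length(noise_sd) != 2 || any(noise_sd < 0)) {
    abort("noise_sd must be two non-negative numbers (temperature, rainfall)")
  }
  set.seed(as.integer(seed))
  lat_centers <- origin[2] + (rows:1 - 0.5) * cellsize   # row 1 = north
  lat_mid <- mean(range(lat_centers))
  lat_field <- matrix(rep(lat_centers, cols), nrow = rows)

  # truncate noise so the temperature bounds survive any draw
  trunc_noise <- function(n, sd, lim) {
    if (sd == 0) return(numeric(n))
    pmin(pmax(rnorm(n, 0, sd), -lim), lim)
  }

  month_grids <- function(make) lapply(seq_len(12), make)
  temperature <- month_grids(function(m) {
    season <- T_amplitude * sin(2 * pi * (m - 1) / 12)
    v <- T_mean + T_gradient * abs(lat_field - lat_mid) + season +
      matrix(trunc_noise(rows * cols, noise_sd[1], 3 * noise_sd[1] + 1e-12),
             nrow = rows)
    v <- pmin(pmax(v, 0), 45)
    raster_grid(v, origin[1], origin[2], cellsize)
  })
  rainfall <- month_grids(function(m) {
    # circular distance in months from the wet-season centre
    dm <- pmin(abs(m - wet_season_center), 12 - abs(m - wet_season_center))
    season <- exp(-(dm / 2.5)^2)
    # wettest at the row centre nearest the grid's central latitude, so the
    # bump attains exactly rain_peak somewhere on the grid
    lat_wet <- lat_centers[which.min(abs(lat_centers - lat_mid))]
    spatial <- exp(-((lat_field - lat_wet) / 8)^2)
    v <- rain_peak * season * spatial +
      matrix(trunc_noise(rows * cols, noise_sd[2], 6 * noise_sd[2]),
             nrow = rows)
    raster_grid(pmax(v, 0), origin[1], origin[2], cellsize)
  })
  list(temperature = temperature, rainfall = rainfall,
       spec = list(rows = rows, cols = cols, T_mean = T_mean,
                   T_amplitude = T_amplitude, T_gradient = T_gradient,
                   rain_peak = rain_peak,
                   wet_season_center = wet_season_center,
                   noise_sd = noise_sd, cellsize = cellsize,
                   origin = origin, seed = as.integer(seed)))
}

#' Generate synthetic resistance observation points
#'
#' Emulates a ground-truthing point set with known placement relative to a
#' risk-class map: `round(n * frac_high)` confirmed-resistant points are
#' placed uniformly inside randomly chosen high-class pixels; the remainder
#' are placed uniformly over all valid pixels (so they may or may not land
#' in a high pixel). The number of points that actually sit in high-class
#' pixels is counted at construction time and recorded, giving an exact
#' by-construction oracle for [overlay_accuracy()].
#'
#' @param classmap An `irmap_raster` of class codes (from [classify_map()]).
#' @param n Number of points (> 0).
#' @param frac_high Fraction of points forced into high-class pixels.
#' @param seed Integer seed (required).
#' @param year Year stamped on every point (default 2022).
#' @return A tibble with columns `lon`, `lat`, `year`, `status`,
#'   `in_high` (logical, by construction), and attributes
#'   `n_high_constructed` and `frac_high_constructed`.
#' @export
synth_points <- function(classmap, n, frac_high, seed, year = 2022) {
  stopifnot(inherits(classmap, "irmap_raster"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("n must be a positive count (empty validation sets are not allowed)")
  }
  if (frac_high < 0 || frac_high > 1) abort("frac_high must lie in [0, 1]")
  v <- classmap$values
  valid <- which(!is.na(v))
  if (length(valid) == 0) abort("classmap has no valid pixels")
  high <- which(!is.na(v) & v == 3)
  if (frac_high > 0 && length(high) == 0) {
    abort("classmap has no high-class pixels but frac_high > 0")
  }
  set.seed(as.integer(seed))
  n_forced <- round(n * frac_high)
  cells <- c(
    if (n_forced > 0) sample(high, n_forced, replace = TRUE),
    if (n - n_forced > 0) sample(valid, n - n_forced, replace = TRUE)
  )
  nr <- nrow(v)
  row <- ((cells - 1) %% nr) + 1
  col <- ((cells - 1) %/% nr) + 1
  # uniform position inside the half-open cell
  u <- runif(n); w <- runif(n)
  lon <- classmap$xllcorner + (col - 1 + u) * classmap$cellsize
  lat <- classmap$yllcorner + (nr - row + w) * classmap$cellsize
  out <- tibble(lon = lon, lat = lat, year = as.integer(year),
                status = "resistant",
                in_high = v[cells] == 3)
  attr(out, "n_high_constructed") <- sum(out$in_high)
  attr(out, "frac_high_constructed") <- sum(out$in_high) / n
  attr(out, "seed") <- as.integer(seed)
  out
}
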