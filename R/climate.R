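# Climate response functions: temperature-dependent adult mortality and
# rainfall/temperature-dependent birth rate (Parham-Michael style forms).
#
# Invalidity is a value, not an exception: where the adult lifespan
# polynomial a T^2 + b T + c is non-positive the mortality (and anything
# built on it) returns NA so that raster maps can carry the cell as nodata
# instead of failing.

#' Temperature-dependent adult mortality rate
#'
#' `mu(T) = 1 / (a T^2 + b T + c)`, where the quadratic is the expected
#' adult lifespan in days. Where the lifespan polynomial is zero or
#' negative the rate is undefined and `NA` is returned; downstream raster
#' operations treat such cells as nodata.
#'
#' @param T Mean temperature (degC); vectorised.
#' @param lh A [life_history_parameters()] object.
#' @return Mortality rate (day^-1), `NA` where invalid.
#' @examples
#' lh <- life_history_parameters()          # parham2010 preset, a = -0.03
#' mortality_rate(20, lh)                   # 1/9.8 = 0.102041
#' lh_printed <- life_history_parameters(preset = "table1_as_printed")
#' mortality_rate(20, lh_printed)           # NA: lifespan negative everywhere
#' @export
mortality_rate <- function(T, lh) {
  lh <- validate_life_history(lh)
  if (!is.numeric(T)) abort("T must be numeric")
  lifespan <- lh$a * T^2 + lh$b * T + lh$c
  out <- ifelse(is.finite(lifespan) & lifespan > 0, 1 / lifespan, NA_real_)
  out[!is.finite(T)] <- NA_real_
  out
}

#' Rainfall suitability factor for oviposition
#'
#' `(4 R (R_L - R) / R_L^2)^3`: a cubed parabola in monthly rainfall `R`
#' that is 0 with no rain, peaks at 1 when `R = R_L / 2`, and falls back to
#' 0 at the rainfall limit `R_L`. Beyond `R_L` breeding sites are assumed
#' washed out and the factor is clamped to 0 (the raw cube would turn
#' negative).
#'
#' @param rain Monthly rainfall (mm, >= 0); vectorised.
#' @param R_L Rainfall limit (mm, > 0).
#' @return Dimensionless factor in \[0, 1\].
#' @examples
#' rainfall_factor(c(0, 25, 50, 75), R_L = 50)
#' @export
rainfall_factor <- function(rain, R_L) {
  if (!is.numeric(R_L) || length(R_L) != 1 || !is.finite(R_L) || R_L <= 0) {
    abort("rainfall limit R_L must be a single positive number")
  }
  if (!is.numeric(rain)) abort("rain must be numeric")
  if (any(rain < 0, na.rm = TRUE)) abort("rain must be >= 0")
  f <- (4 * rain * (R_L - rain) / R_L^2)^3
  f[!is.na(rain) & rain > R_L] <- 0
  f
}

#' Climate-dependent mosquito birth rate
#'
#' Eggs per oviposition times immature survival, scaled by the rainfall
#' suitability factor and by a temperature-dependent adult emergence term:
#'
#' `r(R, T) = B_E thetaE thetaL thetaP * f(R) * x e^(-x) / (2x + 1)`,
#' with `x = k1 T + k2` and `f(R)` from [rainfall_factor()]. The result is
#' floored at 0 (the emergence term can go negative at temperatures cold
#' enough that `x < 0`); if the denominator `2x + 1` is non-positive the
#' rate is undefined and `NA` is returned.
#'
#' @param T Mean temperature (degC); vectorised.
#' @param rain Monthly rainfall (mm, >= 0); vectorised (recycled against `T`).
#' @param lh A [life_history_parameters()] object.
#' @return Birth rate (day^-1), `NA` where undefined.
#' @examples
#' birth_rate(25, 25, life_history_parameters())   # ~1.957
#' @export
birth_rate <- function(T, rain, lh) {
  lh <- validate_life_history(lh)
  if (!is.numeric(T) || !is.numeric(rain)) abort("T and rain must be numeric")
  n <- max(length(T), length(rain))
  T <- rep_len(T, n); rain <- rep_len(rain, n)
  f <- rainfall_factor(rain, lh$R_L)
  x <- lh$k1 * T + lh$k2
  denom <- 2 * x + 1
  emergence <- ifelse(denom > 0, x * exp(-x) / denom, NA_real_)
  r <- lh$B_E * lh$theta_E * lh$theta_L * lh$theta_P * f * emergence
  out <- ifelse(is.na(r), NA_real_, pmax(r, 0))
  out[!is.finite(T)] <- NA_real_
  out
}

#' Add climate-driven rates to a table of climate samples
#'
#' Pipeline verb: given a data frame with temperature and rainfall columns,
#' append the derived mortality and birth rates.
#'
#' @param data A data frame with columns `T` (degC) and `rain` (mm/month).
#' @param lh A [life_history_parameters()] object.
#' @return `data` as a tibble with added columns `mu` and `r`
#'   (`NA` where undefined).
#' @examples
#' tibble::tibble(T = c(18, 25, 32), rain = c(10, 25, 60)) |>
#'   climate_rates(life_history_parameters())
#' @export
climate_rates <- function(data, lh = life_history_parameters()) {
  if (!is.data.frame(data) || !all(c("T", "rain") %in% names(data))) {
    abort("data must be a data frame with columns 'T' and 'rain'")
  }
  dplyr::mutate(tibble::as_tibble(data),
                mu = mortality_rate(.data$T, lh),
                r = birth_rate(.data$T, .data$rain, lh))
}
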