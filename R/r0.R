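# The basic reproduction number for insecticide resistance: closed form,
# climate-driven form, risk classification, and the standard
# next-generation-matrix diagnostic.

#' Basic reproduction number of insecticide resistance (closed form)
#'
#' `R0 = (1 / (mu + mu_i + alpha)) * sqrt(beta (r + gamma) / N)`: the
#' average number of resistant mosquitoes a single resistant mosquito gives
#' rise to over its lifetime. `R0 < 1` means resistance dies out of the
#' population; `R0 > 1` means it propagates across generations.
#'
#' This closed form is the package's authoritative reproduction number,
#' used for all maps and sensitivity results. Note that it is *not* the
#' spectral radius of the standard next-generation matrix of the S-R-M
#' system; [ngm_standard()] computes that quantity as a clearly-labelled
#' diagnostic and the two generally disagree.
#'
#' @inheritParams rhs_model1
#' @return Non-negative numeric scalar.
#' @examples
#' r0_closed_form(model_parameters())   # ~2.89 under the table1 preset
#' @export
r0_closed_form <- function(params) {
  params <- validate_model_parameters(params)
  denom <- params$mu + params$mu_i + params$alpha
  if (denom <= 0) abort("mu + mu_i + alpha must be > 0")
  sqrt(params$beta * (params$r + params$gamma) / params$N) / denom
}

#' Climate-driven basic reproduction number
#'
#' The closed-form reproduction number with the constant birth and death
#' rates replaced by their climate responses: `r <- birth_rate(T, rain)`
#' and `mu <- mortality_rate(T)`. Returns `NA` wherever the mortality (or
#' birth) response is undefined, so raster maps can carry those cells as
#' nodata.
#'
#' `r0_climate()` composes the verified climate responses through the
#' closed form; [r0_climate_direct()] evaluates the single fully-substituted
#' algebraic expression. The two agree to machine precision and the pair is
#' kept as a dual-route consistency check.
#'
#' @param T Mean temperature (degC); vectorised.
#' @param rain Monthly rainfall (mm); vectorised (recycled against `T`).
#' @param params A [model_parameters()] object (its `r` and `mu` fields are
#'   ignored here).
#' @param lh A [life_history_parameters()] object.
#' @return Numeric vector of reproduction numbers, `NA` where undefined.
#' @examples
#' r0_climate(25, 25, model_parameters(), life_history_parameters())  # ~1.87
#' @export
r0_climate <- function(T, rain, params = model_parameters(),
                       lh = life_history_parameters()) {
  params <- validate_model_parameters(params)
  lh <- validate_life_history(lh)
  mu_T <- mortality_rate(T, lh)
  r_RT <- birth_rate(T, rain, lh)
  denom <- mu_T + params$mu_i + params$alpha
  out <- sqrt(params$beta * (r_RT + params$gamma) / params$N) / denom
  out[is.na(mu_T) | is.na(r_RT)] <- NA_real_
  out
}

#' @rdname r0_climate
#' @export
r0_climate_direct <- function(T, rain, params = model_parameters(),
                              lh = life_history_parameters()) {
  params <- validate_model_parameters(params)
  lh <- validate_life_history(lh)
  n <- max(length(T), length(rain))
  T <- rep_len(T, n); rain <- rep_len(rain, n)
  p <- lh$a * T^2 + lh$b * T + lh$c            # adult lifespan (days)
  f <- rainfall_factor(rain, lh$R_L)
  x <- lh$k1 * T + lh$k2
  emergence <- x * exp(-x) / (2 * x + 1)
  r <- pmax(lh$B_E * lh$theta_E * lh$theta_L * lh$theta_P * f * emergence, 0)
  out <- sqrt(params$beta * (r + params$gamma) * p^2 /
                (params$N * (p * (params$mu_i + params$alpha) + 1)^2))
  out[!(is.finite(p) & p > 0) | !(is.finite(x) & 2 * x + 1 > 0)] <- NA_real_
  out
}

#' Classify reproduction numbers into risk classes
#'
#' Map legend thresholds: `low` for `R0 < 1`, `moderate` for
#' `1 <= R0 <= 1.1` (both boundaries inclusive), `high` for `R0 > 1.1`.
#' `NA` in gives `NA` out.
#'
#' @param r0 Numeric vector of reproduction numbers.
#' @param thresholds Length-2 numeric: the low/moderate and moderate/high
#'   boundaries (default `c(1, 1.1)`).
#' @return Ordered factor with levels `low < moderate < high`.
#' @examples
#' classify_risk(c(0.5, 1, 1.05, 1.1, 1.2, NA))
#' @export
classify_risk <- function(r0, thresholds = c(1, 1.1)) {
  if (length(thresholds) != 2 || !is.numeric(thresholds) ||
      thresholds[1] > thresholds[2]) {
    abort("thresholds must be two non-decreasing numbers")
  }
  cls <- ifelse(is.na(r0), NA_character_,
                ifelse(r0 < thresholds[1], "low",
                       ifelse(r0 <= thresholds[2], "moderate", "high")))
  factor(cls, levels = c("low", "moderate", "high"), ordered = TRUE)
}

#' Spectral radius of the standard next-generation matrix (diagnostic)
#'
#' The conventional F V^-1 construction on the infected compartments
#' \{R, M\} of model 1, linearised at the resistance-free equilibrium.
#' Because those compartments decouple at the equilibrium the matrix is
#' diagonal and its spectral radius is simply the larger of the two
#' invasion ratios from [invasion_conditions()]:
#' `max(beta S0 / (N mu), (gamma - alpha) S0 / mu)`.
#'
#' This does **not** reproduce [r0_closed_form()]: the closed form used
#' throughout the package is not the spectral radius of the standard
#' next-generation matrix of the S-R-M system. `ngm_standard()` exists to
#' make that disagreement measurable; its threshold (value vs 1) does
#' agree with the invasion analysis by construction.
#'
#' @inheritParams rhs_model1
#' @return Non-negative numeric scalar.
#' @examples
#' ngm_standard(model_parameters())
#' @export
ngm_standard <- function(params) {
  max(0, invasion_conditions(params)$ratio)
}

#' Reproduction numbers and risk classes for a table of climate samples
#'
#' Pipeline verb: append `r0` and `risk` columns to a data frame of
#' temperature/rainfall samples.
#'
#' @param data Data frame with columns `T` (degC) and `rain` (mm/month).
#' @param params A [model_parameters()] object.
#' @param lh A [life_history_parameters()] object.
#' @param thresholds Risk-class boundaries, see [classify_risk()].
#' @return `data` as a tibble with added `r0` and `risk` columns.
#' @examples
#' tibble::tibble(T = c(20, 25, 30), rain = c(10, 25, 40)) |> r0_table()
#' @export
r0_table <- function(data, params = model_parameters(),
                     lh = life_history_parameters(), thresholds = c(1, 1.1)) {
  if (!is.data.frame(data) || !all(c("T", "rain") %in% names(data))) {
    abort("data must be a data frame with columns 'T' and 'rain'")
  }
  dplyr::mutate(tibble::as_tibble(data),
                r0 = r0_climate(.data$T, .data$rain, params, lh),
                risk = classify_risk(.data$r0, thresholds))
}
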