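# Parameter containers and shipped presets.
#
# Two parameter sets drive everything downstream:
#   * model_parameters()      -- the seven dynamical rates of the S-R-M system
#                                and of the closed-form reproduction number;
#   * life_history_parameters() -- the ten life-history constants feeding the
#                                temperature-dependent mortality mu(T) and the
#                                rainfall/temperature-dependent birth rate r(R,T).

#' Dynamical parameters of the resistance-transmission model
#'
#' Bundle and validate the seven parameters of the susceptible (S), resistant
#' (R), non-resistant-offspring (M) compartmental system and of the basic
#' reproduction number for insecticide resistance.
#'
#' @param r Mosquito birth rate (day^-1).
#' @param beta Transmission probability: chance that a susceptible mosquito
#'   becomes resistant per contact with an insecticide-exposed resistant
#'   mosquito (dimensionless, in \[0, 1\]).
#' @param gamma Probability that a resistant mosquito produces non-resistant
#'   offspring (dimensionless, in \[0, 1\]).
#' @param alpha Rate at which non-resistant offspring of resistant mosquitoes
#'   revert to the susceptible pool (day^-1).
#' @param mu Natural mosquito death rate (day^-1).
#' @param mu_i Insecticide-induced mortality rate (day^-1).
#' @param N Total mosquito population size (individuals, > 0).
#' @param preset Optional preset name; currently `"table1"`, the calibrated
#'   parameter set shipped with the package (`beta = 1`, `gamma = 0.75`,
#'   `alpha = 0.01`, `mu_i = 0.01`, `N = 50`, with desk-scale defaults
#'   `r = 0.75`, `mu = 0.04` for constant-parameter use; in climate-driven
#'   runs `r` and `mu` are replaced by `r(R, T)` and `mu(T)`).
#'   Explicit arguments override preset values.
#'
#' @return An object of class `model_parameters`: a validated named list with
#'   elements `r`, `beta`, `gamma`, `alpha`, `mu`, `mu_i`, `N`.
#'
#' @examples
#' p <- model_parameters()        # the "table1" preset
#' p$beta
#' model_parameters(N = 100)      # override one field
#' @export
model_parameters <- function(r = NULL, beta = NULL, gamma = NULL,
                             alpha = NULL, mu = NULL, mu_i = NULL, N = NULL,
                             preset = "table1") {
  base <- model_parameter_presets(preset)
  given <- list(r = r, beta = beta, gamma = gamma, alpha = alpha,
                mu = mu, mu_i = mu_i, N = N)
  given <- given[!vapply(given, is.null, logical(1))]
  out <- modifyList(base, given)
  validate_model_parameters(out)
}

model_parameter_presets <- function(preset) {
  presets <- list(
    table1 = list(r = 0.75, beta = 1, gamma = 0.75, alpha = 0.01,
                  mu = 0.04, mu_i = 0.01, N = 50)
  )
  if (!preset %in% names(presets)) {
    abort(sprintf("unknown model parameter preset '%s' (available: %s)",
                  preset, paste(names(presets), collapse = ", ")))
  }
  presets[[preset]]
}

validate_model_parameters <- function(x) {
  fields <- c("r", "beta", "gamma", "alpha", "mu", "mu_i", "N")
  missing <- setdiff(fields, names(x))
  if (length(missing)) {
    abort(paste0("model parameters missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- x[fields]
  bad <- names(x)[!vapply(x, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v), logical(1))]
  if (length(bad)) {
    abort(paste0("model parameter(s) not finite scalars: ",
                 paste(bad, collapse = ", ")))
  }
  neg <- names(x)[vapply(x, function(v) v < 0, logical(1))]
  if (length(neg)) {
    abort(paste0("model parameter(s) must be >= 0: ",
                 paste(neg, collapse = ", ")))
  }
  if (x$N <= 0) abort("N must be > 0")
  if (x$beta > 1) abort("beta is a probability and must be <= 1")
  if (x$gamma > 1) abort("gamma is a probability and must be <= 1")
  structure(x, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  for (nm in names(x)) cat(sprintf("  %-6s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Life-history constants for the climate response functions
#'
#' The ten constants that parameterise temperature-dependent adult mortality
#' `mu(T) = 1 / (a T^2 + b T + c)` and the rainfall/temperature-dependent
#' birth rate used for climate-driven reproduction numbers.
#'
#' @param B_E Eggs per oviposition (count).
#' @param theta_E,theta_L,theta_P Daily survival probabilities of eggs,
#'   larvae and pupae (each in \[0, 1\]).
#' @param R_L Rainfall limit (mm / month): rainfall beyond which breeding
#'   sites wash out; the oviposition factor peaks at `R_L / 2`.
#' @param k1,k2 Development-rate constants ((degC day)^-1 and day^-1).
#' @param a,b,c Coefficients of the adult lifespan polynomial
#'   `a T^2 + b T + c` (days), in (degC^2 day)^-1, (degC day)^-1 and day^-1.
#' @param preset One of:
#'   * `"parham2010"` (default): the shipped constants with the standard
#'     quadratic mortality coefficient `a = -0.03`, giving a positive adult
#'     lifespan over the usual tropical temperature range;
#'   * `"table1_as_printed"`: identical except `a = -0.3`. Under this value
#'     the lifespan polynomial is negative at every temperature
#'     (discriminant `b^2 - 4ac < 0` with `a < 0`), so `mortality_rate()` is
#'     invalid everywhere and no map can be produced. It is shipped verbatim
#'     so the discrepancy is visible rather than silently corrected.
#'   Explicit arguments override preset values.
#'
#' @return An object of class `life_history_parameters`.
#'
#' @examples
#' lh <- life_history_parameters()
#' mortality_rate(20, lh)       # ~0.102 day^-1
#' @export
life_history_parameters <- function(B_E = NULL, theta_E = NULL, theta_L = NULL,
                                    theta_P = NULL, R_L = NULL, k1 = NULL,
                                    k2 = NULL, a = NULL, b = NULL, c = NULL,
                                    preset = "parham2010") {
  base <- life_history_presets(preset)
  given <- list(B_E = B_E, theta_E = theta_E, theta_L = theta_L,
                theta_P = theta_P, R_L = R_L, k1 = k1, k2 = k2,
                a = a, b = b, c = c)
  given <- given[!vapply(given, is.null, logical(1))]
  out <- modifyList(base, given)
  validate_life_history(out)
}

life_history_presets <- function(preset) {
  shared <- list(B_E = 200, theta_E = 0.9, theta_L = 0.25, theta_P = 0.75,
                 R_L = 50, k1 = 0.00554, k2 = -0.06737,
                 b = 1.31, c = -4.4)
  presets <- list(
    parham2010 = c(shared, list(a = -0.03)),
    table1_as_printed = c(shared, list(a = -0.3))
  )
  if (!preset %in% names(presets)) {
    abort(sprintf("unknown life-history preset '%s' (available: %s)",
                  preset, paste(names(presets), collapse = ", ")))
  }
  presets[[preset]]
}

validate_life_history <- function(x) {
  fields <- c("B_E", "theta_E", "theta_L", "theta_P", "R_L",
              "k1", "k2", "a", "b", "c")
  missing <- setdiff(fields, names(x))
  if (length(missing)) {
    abort(paste0("life-history parameters missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- x[fields]
  bad <- names(x)[!vapply(x, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v), logical(1))]
  if (length(bad)) {
    abort(paste0("life-history parameter(s) not finite scalars: ",
                 paste(bad, collapse = ", ")))
  }
  for (nm in c("theta_E", "theta_L", "theta_P")) {
    if (x[[nm]] < 0 || x[[nm]] > 1) {
      abort(sprintf("%s is a survival probability and must lie in [0, 1]", nm))
    }
  }
  if (x$R_L <= 0) abort("rainfall limit R_L must be > 0")
  if (x$B_E <= 0) abort("eggs per oviposition B_E must be > 0")
  structure(x, class = "life_history_parameters")
}

#' @export
print.life_history_parameters <- function(x, ...) {
  cat("<life_history_parameters>\n")
  for (nm in names(x)) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Parameters as a one-row tibble
#'
#' @param x A `model_parameters` or `life_history_parameters` object.
#' @param ... Unused.
#' @return A one-row tibble with one column per parameter.
#' @export
as_tibble.model_parameters <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname as_tibble.model_parameters
#' @export
as_tibble.life_history_parameters <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
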