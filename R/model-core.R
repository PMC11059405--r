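# The compartmental core: two S-R-M systems, their resistance-free
# equilibrium, numerical integration, and linear-stability diagnostics.
#
# Model 1 (imperfect vertical transmission; alpha > 0 allows non-resistant
# offspring to re-enter the susceptible pool):
#   dS/dt = r - (mu + mu_i) S - (beta/N) S R - gamma S M + alpha M S
#   dR/dt = (beta/N) S R - mu R
#   dM/dt = gamma S M - alpha M S - mu M
# Model 2 is model 1 with alpha = 0 (perfect vertical transmission).

as_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (!is.numeric(state) || length(state) != 3) {
    abort("state must be three numbers (S, R, M)")
  }
  if (is.null(names(state)) || !all(c("S", "R", "M") %in% names(state))) {
    names(state) <- c("S", "R", "M")
  }
  if (!all(is.finite(state))) abort("state contains non-finite values")
  state[c("S", "R", "M")]
}

#' Right-hand side of the resistance-transmission models
#'
#' Evaluate the time derivatives (dS/dt, dR/dt, dM/dt) of the
#' susceptible/resistant/non-resistant-offspring system. `rhs_model1()` is
#' the imperfect-vertical-transmission variant in which offspring that did
#' not inherit resistance revert to the susceptible class at rate `alpha`;
#' `rhs_model2()` is the perfect-transmission variant, identical to model 1
#' with `alpha` forced to zero (the `alpha` field of `params` is ignored).
#'
#' @param state Population state: a numeric vector or list with elements
#'   `S` (susceptible), `R` (resistant), `M` (non-resistant offspring).
#' @param params A [model_parameters()] object.
#' @return Named numeric vector `c(S = dS/dt, R = dR/dt, M = dM/dt)`
#'   (individuals / day).
#' @examples
#' p <- model_parameters()
#' rhs_model1(c(S = 15, R = 0, M = 0), p)   # resistance-free equilibrium
#' @export
rhs_model1 <- function(state, params) {
  params <- validate_model_parameters(params)
  x <- as_state(state)
  S <- x[["S"]]; R <- x[["R"]]; M <- x[["M"]]
  c(S = params$r - (params$mu + params$mu_i) * S -
      (params$beta / params$N) * S * R - params$gamma * S * M +
      params$alpha * M * S,
    R = (params$beta / params$N) * S * R - params$mu * R,
    M = params$gamma * S * M - params$alpha * M * S - params$mu * M)
}

#' @rdname rhs_model1
#' @export
rhs_model2 <- function(state, params) {
  params <- validate_model_parameters(params)
  params$alpha <- 0
  rhs_model1(state, params)
}

model_rhs <- function(model) {
  model <- match.arg(model, c("model1", "model2"))
  if (model == "model1") rhs_model1 else rhs_model2
}

#' Resistance-free equilibrium
#'
#' The steady state with no resistant mosquitoes and no non-resistant
#' offspring: `S0 = r / (mu + mu_i)`, `R = M = 0`. Both model variants share
#' it, and the right-hand side evaluates to zero there.
#'
#' @inheritParams rhs_model1
#' @return Named numeric vector `c(S, R, M)`.
#' @examples
#' resistance_free_equilibrium(model_parameters())   # S0 = 0.75/0.05 = 15
#' @export
resistance_free_equilibrium <- function(params) {
  params <- validate_model_parameters(params)
  if (params$mu + params$mu_i <= 0) {
    abort("mu + mu_i must be > 0 to define the resistance-free equilibrium")
  }
  c(S = params$r / (params$mu + params$mu_i), R = 0, M = 0)
}

#' Invasion thresholds at the resistance-free equilibrium
#'
#' Linearising either model at the resistance-free equilibrium decouples the
#' R and M compartments, whose per-capita growth rates change sign at the
#' two threshold ratios returned here:
#' `beta * S0 / (N * mu)` for resistant mosquitoes and
#' `(gamma - alpha) * S0 / mu` for non-resistant offspring, with
#' `S0 = r / (mu + mu_i)`. A ratio above 1 means a small seed of the
#' corresponding compartment grows away from the equilibrium; below 1 it
#' dies out. These Jacobian-derived ratios are the package's authoritative
#' stability diagnostics (see [ngm_standard()] for the related spectral
#' radius and its documented disagreement with [r0_closed_form()]).
#'
#' @inheritParams rhs_model1
#' @return A tibble with columns `compartment` ("R", "M") and `ratio`.
#' @examples
#' invasion_conditions(model_parameters())
#' @export
invasion_conditions <- function(params) {
  params <- validate_model_parameters(params)
  if (params$mu <= 0) abort("mu must be > 0 for invasion analysis")
  S0 <- resistance_free_equilibrium(params)[["S"]]
  tibble(
    compartment = c("R", "M"),
    ratio = c(params$beta * S0 / (params$N * params$mu),
              (params$gamma - params$alpha) * S0 / params$mu)
  )
}

#' Integrate the resistance-transmission model
#'
#' Adaptive-step integration (lsoda, relative tolerance 1e-8, absolute
#' tolerance 1e-10) of model 1 or model 2 from an initial state, sampled on
#' a regular output grid. Compartments are population counts: small negative
#' undershoot (above -1e-9) from the integrator is clipped to zero with a
#' warning; anything below that is treated as an integration failure.
#'
#' @inheritParams rhs_model1
#' @param state0 Initial state `c(S, R, M)`, all non-negative.
#' @param t_end Final time (days, > 0).
#' @param dt_out Output sampling interval (days, > 0). Solver steps are
#'   adaptive and independent of this grid.
#' @param model `"model1"` (default) or `"model2"` — always chosen
#'   explicitly, never inferred from `alpha`.
#' @return A tibble of class `irmap_trajectory` with columns
#'   `time`, `S`, `R`, `M`, carrying the parameters and model choice as
#'   attributes.
#' @examples
#' p <- model_parameters()
#' traj <- simulate_model(p, c(S = 15, R = 1, M = 0), t_end = 30)
#' tail(traj)
#' @export
simulate_model <- function(params, state0, t_end, dt_out = 1,
                           model = c("model1", "model2")) {
  params <- validate_model_parameters(params)
  model <- match.arg(model)
  x0 <- as_state(state0)
  if (any(x0 < 0)) abort("initial state must be non-negative")
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end <= 0) {
    abort("t_end must be a positive number of days")
  }
  if (!is.numeric(dt_out) || length(dt_out) != 1 || dt_out <= 0) {
    abort("dt_out must be a positive number of days")
  }
  rhs <- model_rhs(model)
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)

  deriv <- function(t, y, parms) list(unname(rhs(y, parms)))
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = params,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    abort(sprintf("integration failed near t = %g days",
                  sol[nrow(sol), "time"]))
  }
  vals <- as.data.frame(sol)
  undershoot <- min(0, min(as.matrix(vals[c("S", "R", "M")])))
  if (undershoot < -1e-9) {
    abort(sprintf(
      "integrator returned compartment value %.3g below tolerance", undershoot))
  }
  if (undershoot < 0) {
    warn("clipping small negative compartment values (integrator undershoot) to 0")
    vals[c("S", "R", "M")] <- lapply(vals[c("S", "R", "M")], pmax, 0)
  }
  out <- tibble::as_tibble(vals)
  attr(out, "params") <- params
  attr(out, "model") <- model
  class(out) <- c("irmap_trajectory", class(out))
  out
}

#' @export
glance.irmap_trajectory <- function(x, ...) {
  tibble(
    model = attr(x, "model"),
    t_end = max(x$time),
    S_final = x$S[nrow(x)],
    R_final = x$R[nrow(x)],
    M_final = x$M[nrow(x)],
    R_invaded = x$R[nrow(x)] > x$R[1]
  )
}

#' @export
tidy.irmap_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), cols = c("S", "R", "M"),
                      names_to = "compartment", values_to = "count")
}

#' Write a trajectory to CSV
#'
#' Columns `time,S,R,M`, no row names.
#'
#' @param trajectory An `irmap_trajectory` (or any data frame with those
#'   columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory)[c("time", "S", "R", "M")],
                   path, row.names = FALSE)
  invisible(path)
}
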