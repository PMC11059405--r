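# Sensitivity of the reproduction number to its parameters: local +/-10%
# perturbations (exact scaling laws of the closed form) and global
# Latin-hypercube / partial-rank-correlation analysis.

PARAM_NAMES <- c("r", "beta", "gamma", "alpha", "mu", "mu_i", "N")

# Closed-form R0 without the probability-bound checks: perturbation and
# hypercube sampling legitimately push beta or gamma a little above 1, and
# the formula extends smoothly there.
r0_raw <- function(q) {
  denom <- q$mu + q$mu_i + q$alpha
  if (denom <= 0 || q$N <= 0) abort("mu + mu_i + alpha and N must be > 0")
  sqrt(q$beta * (q$r + q$gamma) / q$N) / denom
}

#' Local perturbation of the reproduction number
#'
#' Multiply one parameter by `(1 + delta)`, recompute the closed-form
#' reproduction number, and report the signed percent change
#' `100 * (R0_new - R0_base) / R0_base`. For `beta` and `N` the ratio is a
#' pure scaling law of the closed form and independent of the baseline
#' (`sqrt(1 + delta)` and `1 / sqrt(1 + delta)`); for the other parameters
#' it depends on the baseline values.
#'
#' @inheritParams rhs_model1
#' @param which Parameter name(s) to perturb; default all seven.
#' @param delta Signed perturbation fraction(s), e.g. `0.1` for +10%;
#'   each `which` is crossed with each `delta`.
#' @return A tibble with columns `parameter`, `delta`, `r0_base`,
#'   `r0_perturbed`, `pct_change`.
#' @examples
#' perturb_r0(model_parameters(), which = "beta", delta = 0.1)  # +4.88%
#' perturb_r0(model_parameters(), delta = c(-0.1, 0.1))         # full table
#' @export
perturb_r0 <- function(params, which = PARAM_NAMES, delta = 0.1) {
  params <- validate_model_parameters(params)
  bad <- setdiff(which, PARAM_NAMES)
  if (length(bad)) {
    abort(sprintf("unknown parameter(s): %s (expected one of %s)",
                  paste(bad, collapse = ", "),
                  paste(PARAM_NAMES, collapse = ", ")))
  }
  base <- r0_closed_form(params)
  if (base <= 0) abort("baseline R0 must be > 0 to report percent changes")
  grid <- tidyr::expand_grid(parameter = which, delta = delta)
  grid |>
    dplyr::mutate(
      r0_base = base,
      r0_perturbed = purrr::map2_dbl(.data$parameter, .data$delta, function(p, d) {
        q <- unclass(params)
        q[[p]] <- q[[p]] * (1 + d)
        r0_raw(q)
      }),
      pct_change = 100 * (.data$r0_perturbed - .data$r0_base) / .data$r0_base
    )
}

#' Latin hypercube sample of the parameter space
#'
#' Stratified sampling: for each parameter the `n` draws fall one per
#' equal-width stratum of its range, with strata independently permuted
#' across parameters. Deterministic under `seed`.
#'
#' @param ranges Named list of `c(low, high)` bounds, one per parameter, or
#'   a data frame with columns `parameter`, `low`, `high`.
#' @param n Number of samples (>= 10).
#' @param seed Integer seed (required: every stochastic entry point in the
#'   package is explicitly seeded).
#' @return An `n` x `length(ranges)` tibble, one column per parameter.
#' @examples
#' lhs_sample(list(beta = c(0.5, 1), N = c(40, 60)), n = 20, seed = 1)
#' @export
lhs_sample <- function(ranges, n, seed) {
  if (is.data.frame(ranges)) {
    stopifnot(all(c("parameter", "low", "high") %in% names(ranges)))
    ranges <- setNames(
      purrr::map2(ranges$low, ranges$high, c), ranges$parameter)
  }
  if (is.null(names(ranges)) || any(names(ranges) == "")) {
    abort("ranges must be named per parameter")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 10) {
    abort("n must be a single count >= 10")
  }
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || !all(is.finite(rg)) || rg[1] >= rg[2]) {
      abort(sprintf("degenerate range for '%s': need finite low < high", nm))
    }
  }
  set.seed(as.integer(seed))
  unit <- lhs::randomLHS(as.integer(n), length(ranges))
  scaled <- purrr::imap(ranges, function(rg, nm) {
    j <- match(nm, names(ranges))
    rg[1] + unit[, j] * (rg[2] - rg[1])
  })
  tibble::as_tibble(scaled)
}

#' Partial rank correlation coefficients
#'
#' Rank-based global sensitivity: every sampled parameter column and the
#' model output are rank-transformed; for each parameter, the residuals of
#' its ranks regressed on all other parameters' ranks are correlated with
#' the residuals of the output ranks regressed on the same covariates. The
#' p-value comes from the t statistic with `n - 2 - k` degrees of freedom,
#' `k` being the number of controlled covariates. A PRCC near +1 (-1) means
#' the parameter monotonically increases (decreases) the output after
#' controlling for the others.
#'
#' @param samples A data frame / matrix of sampled parameter values (e.g.
#'   from [lhs_sample()]); no constant columns.
#' @param outputs Numeric vector of model outputs, one per sample row.
#' @return A tibble of class `irmap_prcc` with columns `parameter`, `prcc`,
#'   `statistic`, `p_value`, `n_samples`.
#' @examples
#' s <- lhs_sample(list(beta = c(0.5, 1), N = c(40, 60)), n = 100, seed = 1)
#' prcc(s, with(s, sqrt(beta / N)))
#' @export
prcc <- function(samples, outputs) {
  X <- as.data.frame(samples)
  if (!is.numeric(outputs) || length(outputs) != nrow(X)) {
    abort("outputs must be a numeric vector with one value per sample row")
  }
  if (ncol(X) < 1) abort("samples must have at least one column")
  const <- names(X)[vapply(X, function(v) length(unique(v)) < 2, logical(1))]
  if (length(const)) {
    abort(paste0("rank-degenerate (constant) column(s): ",
                 paste(const, collapse = ", ")))
  }
  n <- nrow(X)
  p <- ncol(X)
  Rx <- vapply(X, rank, numeric(n))
  Ry <- rank(outputs)
  k <- p - 1                                  # covariates controlled for
  df <- n - 2 - k
  if (df < 1) abort("too few samples for the number of parameters")
  res <- purrr::map(seq_len(p), function(j) {
    Z <- cbind(1, Rx[, -j, drop = FALSE])
    # residualise both the parameter's ranks and the output ranks on the
    # other parameters' ranks
    beta_x <- qr.coef(qr(Z), Rx[, j]); beta_x[is.na(beta_x)] <- 0
    beta_y <- qr.coef(qr(Z), Ry);      beta_y[is.na(beta_y)] <- 0
    ex <- Rx[, j] - Z %*% beta_x
    ey <- Ry - Z %*% beta_y
    if (sd(ex) == 0) {
      abort(paste0("rank-degenerate input: column '", colnames(Rx)[j],
                   "' is collinear with the others"))
    }
    if (sd(ey) == 0) {
      abort(paste0("outputs are rank-degenerate: fully explained by the ",
                   "columns other than '", colnames(Rx)[j], "'"))
    }
    r <- as.numeric(cor(ex, ey))
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    tibble(parameter = colnames(Rx)[j], prcc = r, statistic = tstat,
           p_value = 2 * pt(-abs(tstat), df))
  })
  out <- dplyr::bind_rows(res)
  out$n_samples <- n
  class(out) <- c("irmap_prcc", class(out))
  out
}

#' Global sensitivity of the reproduction number (LHS + PRCC)
#'
#' Convenience pipeline: Latin-hypercube sample all seven parameters in a
#' uniform band around a baseline, evaluate the closed-form reproduction
#' number at every sample, and compute partial rank correlation
#' coefficients. Sampling ranges default to +/-20% around the baseline
#' (the range choice is a package default, overridable via `ranges`).
#'
#' @inheritParams rhs_model1
#' @param n Number of hypercube samples.
#' @param span Half-width of the uniform band as a fraction of each
#'   baseline value (default 0.2).
#' @param seed Integer seed.
#' @param ranges Optional explicit ranges (as in [lhs_sample()]),
#'   overriding `span`.
#' @return An `irmap_prcc` tibble (see [prcc()]) with the seed recorded as
#'   an attribute and `seed` column.
#' @examples
#' r0_prcc(model_parameters(), n = 200, seed = 42)
#' @export
r0_prcc <- function(params = model_parameters(), n = 1000, span = 0.2,
                    seed, ranges = NULL) {
  params <- validate_model_parameters(params)
  if (is.null(ranges)) {
    ranges <- purrr::map(unclass(params)[PARAM_NAMES],
                         function(v) c(v * (1 - span), v * (1 + span)))
  }
  samples <- lhs_sample(ranges, n, seed)
  outputs <- purrr::pmap_dbl(samples, function(...) {
    r0_raw(modifyList(unclass(params), list(...)))
  })
  out <- prcc(samples, outputs)
  out$seed <- as.integer(seed)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' @export
tidy.irmap_prcc <- function(x, ...) {
  tibble(term = x$parameter, estimate = x$prcc,
         statistic = x$statistic, p.value = x$p_value)
}

#' @export
glance.irmap_prcc <- function(x, ...) {
  tibble(n_samples = x$n_samples[1],
         n_parameters = nrow(x),
         seed = if ("seed" %in% names(x)) x$seed[1] else NA_integer_)
}
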