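test_that("closed-form reproduction number matches direct evaluation", {
  p <- baseline_params()
  # (1/0.06) * sqrt(1 * 1.5 / 50)
  expect_equal(r0_closed_form(p), sqrt(0.03) / 0.06, tolerance = 1e-12)
  expect_equal(r0_closed_form(p), 2.8868, tolerance = 1e-4)
  expect_equal(r0_closed_form(model_parameters(beta = 0, gamma = 0, r = 0)), 0)
  expect_error(r0_closed_form(model_parameters(mu = 0, mu_i = 0, alpha = 0)),
               "> 0")

  # pure scaling law in beta: sqrt(1.1), independent of the baseline
  set.seed(21)
  for (i in 1:10) {
    q <- random_params()
    q2 <- q; q2$beta <- q2$beta * 0.9   # stay within [0, 1]
    expect_equal(r0_closed_form(q2) / r0_closed_form(q), sqrt(0.9),
                 tolerance = 1e-12)
  }
})

test_that("climate-driven R0 composes the climate responses through the closed form", {
  p <- baseline_params()
  lh <- lh_working()
  expect_equal(r0_climate(25, 25, p, lh), 1.8740571, tolerance = 1e-6)

  # the fully-substituted algebraic form and the composed route agree to
  # machine precision over a temperature x rainfall grid
  grid <- expand.grid(T = seq(5, 40, length.out = 50),
                      rain = seq(0, 80, length.out = 50))
  a <- r0_climate(grid$T, grid$rain, p, lh)
  b <- r0_climate_direct(grid$T, grid$rain, p, lh)
  expect_identical(is.na(a), is.na(b))
  expect_lt(max(abs(a - b), na.rm = TRUE), 1e-12)

  # the composed route equals the closed form with substituted rates
  idx <- which(!is.na(a))[seq(1, sum(!is.na(a)), length.out = 20)]
  for (i in idx) {
    q <- unclass(p)
    q$r <- birth_rate(grid$T[i], grid$rain[i], lh)
    q$mu <- mortality_rate(grid$T[i], lh)
    expect_equal(a[i], r0_closed_form(irmap:::validate_model_parameters(q)),
                 tolerance = 1e-14)
  }
})

test_that("climate R0 handles zero rain and undefined mortality", {
  p <- baseline_params()
  lh <- lh_working()
  # rain = 0: the birth term vanishes
  expect_equal(r0_climate(25, 0, p, lh),
               sqrt(p$beta * p$gamma / p$N) /
                 (mortality_rate(25, lh) + p$mu_i + p$alpha),
               tolerance = 1e-12)
  # invalid mortality propagates as NA
  expect_true(is.na(r0_climate(200, 25, p, lh)))
  lh_printed <- life_history_parameters(preset = "table1_as_printed")
  expect_true(all(is.na(r0_climate(15:35, 25, p, lh_printed))))
})

test_that("risk classification follows the map-legend thresholds", {
  expect_equal(as.character(classify_risk(c(0.5, 1.05, 1.2))),
               c("low", "moderate", "high"))
  # boundary convention: [1, 1.1] is moderate, both ends inclusive
  expect_equal(as.character(classify_risk(c(1, 1.1))),
               c("moderate", "moderate"))
  expect_true(is.na(classify_risk(NA_real_)))
  expect_true(is.ordered(classify_risk(0.5)))
  expect_error(classify_risk(1, thresholds = c(2, 1)), "non-decreasing")
})

test_that("standard next-generation spectral radius equals the larger invasion ratio", {
  p <- baseline_params()
  # max(beta*S0/(N*mu), (gamma-alpha)*S0/mu) = max(7.5, 0.74*15/0.04)
  expect_equal(ngm_standard(p), 277.5)
  expect_equal(ngm_standard(model_parameters(beta = 0, gamma = 0.25,
                                             alpha = 0.25)), 0)
  # threshold agreement with the invasion analysis, and documented
  # disagreement with the closed form
  set.seed(22)
  for (i in 1:20) {
    q <- random_params()
    if (q$mu == 0) next
    expect_identical(ngm_standard(q) > 1,
                     any(invasion_conditions(q)$ratio > 1))
  }
  expect_false(isTRUE(all.equal(ngm_standard(p), r0_closed_form(p))))
})

test_that("closed-form R0 is monotone in each parameter", {
  # strictly increasing in beta, r, gamma; strictly decreasing in
  # N, mu, mu_i, alpha -- finite differences at random parameter points
  set.seed(23)
  up <- c("beta", "r", "gamma")
  down <- c("N", "mu", "mu_i", "alpha")
  for (i in 1:50) {
    q <- random_params()
    base <- r0_closed_form(q)
    for (nm in c(up, down)) {
      q2 <- unclass(q)
      q2[[nm]] <- q2[[nm]] * 1.01 + 1e-6
      delta <- irmap:::r0_raw(q2) - base
      if (nm %in% up) expect_gt(delta, 0) else expect_lt(delta, 0)
    }
  }
})

test_that("r0_table classifies a climate sample table", {
  out <- tibble::tibble(T = c(20, 25, 30), rain = c(10, 25, 40)) |>
    r0_table()
  expect_named(out, c("T", "rain", "r0", "risk"))
  expect_equal(out$r0[2], 1.8740571, tolerance = 1e-6)
  expect_equal(as.character(out$risk[2]), "high")
})
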