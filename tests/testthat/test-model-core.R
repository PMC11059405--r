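test_that("right-hand sides reproduce hand-evaluated derivatives", {
  p <- baseline_params()  # r=0.75, beta=1, gamma=0.75, alpha=0.01,
                          # mu=0.04, mu_i=0.01, N=50

  # the resistance-free equilibrium is stationary
  expect_equal(unname(rhs_model1(c(S = 15, R = 0, M = 0), p)), c(0, 0, 0))
  expect_equal(unname(rhs_model2(c(S = 15, R = 0, M = 0), p)), c(0, 0, 0))

  # term-by-term hand evaluation at S=10, R=5, M=2
  expect_equal(unname(rhs_model1(c(S = 10, R = 5, M = 2), p)),
               c(-15.55, 0.8, 14.72))
  # model 2: dM/dt = gamma*S*M - mu*M = 15 - 0.08
  expect_equal(rhs_model2(c(S = 10, R = 5, M = 2), p)[["M"]], 14.92)

  expect_error(rhs_model1(c(S = NaN, R = 0, M = 0), p), "finite")
})

test_that("model 2 is model 1 with alpha = 0, for random states and parameters", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_params()
    x <- random_state()
    p0 <- p; p0$alpha <- 0
    expect_identical(rhs_model2(x, p), rhs_model1(x, p0))
  }
})

test_that("resistance-free equilibrium is r/(mu+mu_i) and annihilates the rhs", {
  p <- baseline_params()
  expect_equal(unname(resistance_free_equilibrium(p)), c(15, 0, 0))
  expect_equal(unname(resistance_free_equilibrium(model_parameters(r = 0))),
               c(0, 0, 0))
  expect_error(resistance_free_equilibrium(model_parameters(mu = 0, mu_i = 0)),
               "mu")

  set.seed(12)
  for (i in 1:25) {
    p <- random_params()
    rfe <- resistance_free_equilibrium(p)
    expect_equal(unname(rhs_model1(rfe, p)), c(0, 0, 0), tolerance = 1e-14)
    expect_equal(unname(rhs_model2(rfe, p)), c(0, 0, 0), tolerance = 1e-14)
  }
})

test_that("invasion ratios match the Jacobian at the equilibrium", {
  p <- baseline_params()
  ic <- invasion_conditions(p)
  expect_equal(ic$ratio[ic$compartment == "R"], 7.5)      # (1/50)*15/0.04
  expect_equal(invasion_conditions(model_parameters(beta = 0))$ratio[1], 0)
  p_eq <- model_parameters(gamma = 0.25, alpha = 0.25)
  expect_equal(invasion_conditions(p_eq)$ratio[2], 0)
  expect_error(invasion_conditions(model_parameters(mu = 0)), "mu")
})

test_that("a trajectory started at the equilibrium stays there", {
  p <- baseline_params()
  rfe <- resistance_free_equilibrium(p)
  traj <- simulate_model(p, rfe, t_end = 200, dt_out = 10)
  expect_true(all(abs(traj$S - rfe[["S"]]) <= 1e-8 * rfe[["S"]]))
  expect_true(all(traj$R == 0) && all(traj$M == 0))
})

test_that("a resistant seed decays below the invasion threshold and grows above it", {
  # below: beta*S0/(N*mu) < 1  (beta small)
  p_dec <- model_parameters(beta = 0.1, gamma = 0, N = 50)  # ratio 0.75
  expect_lt(invasion_conditions(p_dec)$ratio[1], 1)
  rfe <- resistance_free_equilibrium(p_dec)
  traj <- simulate_model(p_dec, rfe + c(S = 0, R = 1, M = 0), t_end = 400,
                         dt_out = 10)
  expect_lt(traj$R[nrow(traj)], traj$R[1])
  expect_lt(traj$R[nrow(traj)], 0.1)

  # above: the table1 baseline has ratio 7.5
  p_gro <- baseline_params()
  expect_gt(invasion_conditions(p_gro)$ratio[1], 1)
  rfe <- resistance_free_equilibrium(p_gro)
  traj <- simulate_model(p_gro, rfe + c(S = 0, R = 1, M = 0), t_end = 10,
                         dt_out = 0.5)
  expect_gt(traj$R[2], traj$R[1])
})

test_that("output sampling does not change the solution (grid independence)", {
  p <- baseline_params()
  x0 <- c(S = 10, R = 2, M = 1)
  a <- simulate_model(p, x0, t_end = 40, dt_out = 2)
  b <- simulate_model(p, x0, t_end = 40, dt_out = 1)
  shared <- match(a$time, b$time)
  for (cc in c("S", "R", "M")) {
    expect_equal(a[[cc]], b[[cc]][shared], tolerance = 1e-6)
  }
})

test_that("simulate validates inputs and records metadata", {
  p <- baseline_params()
  expect_error(simulate_model(p, c(S = -1, R = 0, M = 0), 10), "non-negative")
  expect_error(simulate_model(p, c(S = 1, R = 0, M = 0), -5), "t_end")
  traj <- simulate_model(p, c(S = 15, R = 1, M = 0), 20, model = "model2")
  expect_s3_class(traj, "irmap_trajectory")
  expect_identical(attr(traj, "model"), "model2")
  g <- glance(traj)
  expect_named(g, c("model", "t_end", "S_final", "R_final", "M_final",
                    "R_invaded"))
  long <- tidy(traj)
  expect_setequal(unique(long$compartment), c("S", "R", "M"))
})

test_that("trajectories round-trip through CSV", {
  p <- baseline_params()
  traj <- simulate_model(p, c(S = 15, R = 1, M = 0.5), 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- utils::read.csv(f)
  expect_identical(names(back), c("time", "S", "R", "M"))
  expect_equal(back$R, traj$R, tolerance = 1e-12)
})
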