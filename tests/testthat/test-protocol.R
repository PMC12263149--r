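test_that("the clamped-glucose recovery matches an independent ODE
           integration of the inactivation cycle", {
  b <- preset_params("B")
  G_min <- 90
  beta0 <- 0.0138
  g <- inactivation_fraction(G_min, b$K_g)
  cycle <- function(t, y, p) {
    list(c(-b$k_IN * g * y[1] + b$k_RE * y[2],
           -b$k_RE * y[2] + b$k_IN * g * y[1]))
  }
  out <- deSolve::ode(y = c(beta0, b$beta_TOT - beta0),
                      times = seq(0, 80, by = 1), func = cycle, parms = NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-13)
  closed <- beta_trajectory(out[, 1], G_min, beta0, b)
  expect_lt(max(abs(closed - out[, 2]) / closed), 1e-6)
  # endpoints of the closed form
  expect_equal(beta_trajectory(0, G_min, beta0, b), beta0)
  expect_equal(beta_trajectory(1e6, G_min, beta0, b),
               steady_beta(G_min, b), tolerance = 1e-12)
})

test_that("maintenance insulin solves the fasting balance quadratic", {
  p <- canonical_parameters()
  I <- insulin_for_target(110, p)
  expect_equal(I, 7.05, tolerance = 1e-3)
  # it is a root of the stated quadratic
  expect_equal(p$S_I * 110 * I^2 + (p$S_E * 110 + p$S_I * 110 * p$I_0) * I +
                 p$S_E * 110 * p$I_0 - p$m_0, 0, tolerance = 1e-8)
  # zero insulin suffices exactly at the no-insulin balance point
  expect_equal(insulin_for_target(p$m_0 / (p$S_E * p$I_0), p), 0,
               tolerance = 1e-10)
  # strictly decreasing in the glucose target
  v <- insulin_for_target(seq(70, 300, by = 5), p)
  expect_true(all(diff(v) < 0))
})

test_that("the dose schedule starts at the full replacement rate, never
           increases, and decays exponentially", {
  b <- preset_params("B")
  # with no endogenous secretion the dose is exactly gamma * I*
  expect_equal(dose_schedule(0, 90, 0, b),
               b$gamma * insulin_for_target(90, b))
  pr <- optimal_protocol(90, beta_start = 0.0138, params = b)
  s <- pr$schedule
  expect_true(all(diff(s$F_I) <= 1e-9))
  # log of the gap to the asymptotic dose is affine in t before the floor
  F_inf <- b$gamma * pr$I_star -
    steady_beta(90, b) * b$c_max * secretion_fraction(90, b$K_f)
  lg <- log(s$F_I[s$F_I > 0] - F_inf)
  expect_lt(max(abs(diff(diff(lg)))), 1e-8)
  # when asymptotic secretion at the target exceeds the maintenance need
  # (targets above the fasting fixed point), the dose floors in finite
  # time; for aggressive targets insulin is needed indefinitely
  p_hi <- optimal_protocol(115, beta_start = 0.0138, params = b)
  expect_true(is.finite(p_hi$dose_floor_time))
  expect_equal(min(p_hi$schedule$F_I), 0)
  p_lo <- optimal_protocol(70, beta_start = 0.0138, params = b)
  expect_identical(p_lo$dose_floor_time, Inf)
  expect_true(all(p_lo$schedule$F_I > 0))
})

test_that("remission time rises with the glucose target and diverges at
           the untreated fixed point", {
  b <- preset_params("B")
  fp <- preset_fp("B")
  beta0 <- min(fp$beta[fp$stability == "stable"])
  curve <- remission_curve(c(85, 90, 95, 100, 105), beta_start = beta0,
                           params = b)
  expect_true(all(diff(curve$time_to_remission) > 0))
  expect_true(all(is.finite(curve$time_to_remission)))
  # at or above the untreated fasting fixed point: never
  expect_identical(time_to_remission(110, beta0, b), Inf)
  expect_identical(time_to_remission(150, beta0, b), Inf)
  # already at the target: immediate
  tgt <- max(fp$beta[fp$stability == "stable"])
  expect_identical(time_to_remission(90, tgt, b), 0)
  # continuity on the finite domain: a fine grid has no jumps
  fine <- remission_curve(seq(100, 109, by = 0.5), beta_start = beta0,
                          params = b)
  expect_lt(max(diff(fine$time_to_remission)), 10)
})

test_that("simulating the titrated protocol reproduces the closed form", {
  b <- no_death(preset_params("B"))
  fp <- preset_fp("B")
  beta0 <- min(fp$beta[fp$stability == "stable"])
  G_min <- 90
  y0 <- system_state(G = G_min, I = insulin_for_target(G_min, b),
                     beta = beta0, beta_IN = b$beta_TOT - beta0,
                     c = b$c_max)
  sc <- kpd_scenario(
    scenario_segment(30, "fasting", treatment_titrated(G_min)),
    initial_state = y0)
  sim <- simulate_scenario(sc, b)
  expect_lt(max(abs(sim$daily$G_mean - G_min)), 1)
  at_days <- sim$trajectory[sim$trajectory$t %in% 1:30, ]
  closed <- beta_trajectory(at_days$t, G_min, beta0, b)
  expect_lt(max(abs(at_days$beta - closed)), 1e-3)
})
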