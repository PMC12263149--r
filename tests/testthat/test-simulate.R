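test_that("meal pulses integrate to the stated fraction of daily hepatic
           production", {
  p <- canonical_parameters()
  tt <- seq(0, 1, by = 1 / (24 * 360))  # 10-second grid
  dt <- diff(tt)
  for (plan in c("normal", "high_sugar", "fasting")) {
    M <- meal_flux(plan, tt, p)
    daily <- sum(dt * (head(M, -1) + tail(M, -1)) / 2)
    target <- switch(plan, normal = 0.03 * 864, high_sugar = 0.70 * 864,
                     fasting = 0)
    expect_equal(daily, target, tolerance = 1e-3)
  }
  expect_equal(0.03 * 864, 25.92)
  expect_equal(0.70 * 864, 604.8)
  # three identical one-hour pulses
  M <- meal_flux("normal", tt, p)
  expect_identical(sum(abs(diff(M > 0))), 6L)
  expect_error(meal_flux("brunch", 0.5), "should be one of")
})

test_that("long constant-condition simulations settle on the equilibria
           module's fixed points", {
  b <- no_death(preset_params("B"))
  fp <- preset_fp("B")
  st <- fp[fp$stability == "stable", ]
  for (i in 1:2) {
    y0 <- state_at_fp(st[i, ], b)
    y0[["G"]] <- y0[["G"]] * 1.08
    y0[["beta"]] <- y0[["beta"]] * 0.92
    y0[["beta_IN"]] <- b$beta_TOT - y0[["beta"]]
    out <- integrate_constant(y0, 400, b)
    expect_lt(abs(out[nrow(out), "G"] - st$G[i]), 0.5)
    # the pool is conserved along the whole trajectory without death
    tot <- out[, "beta"] + out[, "beta_IN"]
    expect_lt(max(abs(tot - tot[1])), 1e-8)
  }
})

test_that("trajectories from either side of the unstable threshold diverge
           to the two different attractors", {
  b <- no_death(preset_params("B"))
  fp <- preset_fp("B")
  bu <- fp$beta[fp$stability == "unstable"]
  st <- fp[fp$stability == "stable", ]
  G_mid <- fp$G[fp$stability == "unstable"]
  ends <- vapply(c(1.1, 0.9), function(mult) {
    y0 <- c(G = G_mid, I = fp$I[fp$stability == "unstable"],
            beta = bu * mult, beta_IN = b$beta_TOT - bu * mult, c = b$c_max)
    out <- integrate_constant(y0, 600, b)
    out[nrow(out), "G"]
  }, numeric(1))
  expect_lt(abs(ends[1] - min(st$G)), 0.5)
  expect_lt(abs(ends[2] - max(st$G)), 0.5)
})

test_that("daily aggregates respect their ordering invariants", {
  d <- sim_B_treated()$daily
  expect_true(all(d$G_mean >= d$G_min - 1e-9))
  expect_true(all(d$G_mean <= d$G_max + 1e-9))
  # total pool is non-increasing (permanent death only removes cells)
  expect_true(all(diff(d$beta_tot) <= 1e-9))
  ev <- sim_B_treated()$events
  expect_true(!is.unsorted(ev$t_day))
})

test_that("halving the solver tolerances leaves daily glucose unchanged to
           well under 0.1 mg/dL", {
  b <- preset_params("B")
  sc <- kpd_scenario(scenario_segment(6, "high_sugar"))
  tight <- simulate_scenario(sc, b)
  loose <- simulate_scenario(sc, b,
                             solver = solver_config(rtol = 2e-8, atol = 2e-10))
  expect_lt(max(abs(tight$daily$G_mean - loose$daily$G_mean)), 0.1)
})

test_that("event annotation handles quiet, remitting and relapsing
           courses", {
  mk_daily <- function(G, insulin) {
    tibble::tibble(day = seq_along(G), G_mean = G, on_insulin = insulin)
  }
  # constant normoglycemia: nothing to report
  quiet <- detect_events(mk_daily(rep(100, 40), rep(FALSE, 40)))
  expect_identical(nrow(quiet), 0L)
  # crisis, treatment, confirmed remission, later relapse
  G <- c(rep(120, 5), rep(350, 5), rep(95, 10), rep(100, 20), rep(160, 10))
  ins <- c(rep(FALSE, 5), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 30))
  ev <- detect_events(mk_daily(G, ins))
  expect_identical(ev$kind, c("crisis_onset", "treatment_start",
                              "treatment_end", "remission", "relapse"))
  expect_equal(ev$t_day[ev$kind == "crisis_onset"], 6)
  expect_equal(ev$t_day[ev$kind == "treatment_end"], 20)
  expect_equal(ev$t_day[ev$kind == "relapse"], 41)
  # an uncontrolled run shorter than the confirmation window is not relapse
  G2 <- c(rep(100, 5), rep(160, 3), rep(100, 22))
  ins2 <- c(rep(TRUE, 2), rep(FALSE, 28))
  ev2 <- detect_events(mk_daily(G2, ins2))
  expect_false("relapse" %in% ev2$kind)
})

test_that("scenario segments are contiguous and validated", {
  expect_error(scenario_segment(-3, "normal"), "positive")
  expect_error(kpd_scenario(), "at least one segment")
  s <- sim_B_treated()$segments
  expect_equal(s$start_day[-1], s$end_day[-nrow(s)])
})
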