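test_that("parameter validation enforces positivity and K_g > K_f", {
  p <- canonical_parameters()
  expect_s3_class(p, "kpd_parameters")
  expect_error(update_parameters(p, S_I = -0.1), "strictly positive")
  expect_error(update_parameters(p, K_g = p$K_f / 2), "K_g must exceed K_f")
  expect_error(update_parameters(p, nonsense = 1), "unknown parameter")
  expect_error(validate_parameters(unclass(p)[-1]), "missing parameter")
})

test_that("parameter sets round-trip through the JSON config format", {
  p <- preset_params("C")
  f <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, f)
  p2 <- read_parameters(f)
  expect_equal(unclass(p), unclass(p2))
  expect_error(read_parameters(file.path(tempdir(), "missing_params.json")),
               "not found")
})

test_that("the rhs vanishes at an equilibrium of the reduced system", {
  p <- no_death(preset_params("B"))
  fp <- preset_fp("B")
  for (i in which(fp$stability == "stable")) {
    y <- state_at_fp(fp[i, ], p)
    d <- kpd_rhs(y, 0, p, exogenous_schedule(), adaptation_policy())
    # derivatives are zero relative to the natural scale of each flux
    expect_lt(abs(d[["G"]]), 1e-6 * p$m_0 / p$I_0)
    expect_lt(abs(d[["I"]]), 1e-6 * p$gamma * y[["I"]])
    expect_lt(abs(d[["beta"]]), 1e-8)
    expect_lt(abs(d[["beta_IN"]]), 1e-8)
    expect_identical(d[["c"]], 0)
  }
})

test_that("the beta pool is conserved exactly when death is off", {
  p <- no_death(preset_params("B"))
  sched <- exogenous_schedule(M = 100, F_I = 50)
  set.seed(42)
  for (i in 1:20) {
    y <- c(G = runif(1, 1, 800), I = runif(1, 0.1, 20),
           beta = runif(1), beta_IN = runif(1), c = p$c_max)
    d <- kpd_rhs(y, 0.3, p, sched, adaptation_policy())
    expect_equal(d[["beta"]] + d[["beta_IN"]], 0, tolerance = 1e-14)
  }
  # and with death on, the pool derivative is non-positive
  pk <- preset_params("D")
  d <- kpd_rhs(c(G = 300, I = 2, beta = 0.3, beta_IN = 0.5, c = pk$c_max),
               0, pk, sched, adaptation_policy())
  expect_lt(d[["beta"]] + d[["beta_IN"]], 0)
})

test_that("a fully active pool at zero glucose is stationary", {
  p <- preset_params("B")
  y <- c(G = 0, I = 0, beta = p$beta_TOT, beta_IN = 0, c = p$c_max)
  d <- kpd_rhs(y, 0, p, exogenous_schedule(), adaptation_policy())
  expect_identical(d[["beta"]], 0)
  expect_identical(d[["beta_IN"]], 0)
})

test_that("rhs is consistent with finite differences of a trajectory", {
  p <- no_death(preset_params("B"))
  fp <- preset_fp("B")
  y0 <- state_at_fp(fp[1, ], p)
  y0[["G"]] <- y0[["G"]] * 1.3   # off equilibrium so derivatives are nonzero
  out <- integrate_constant(y0, 2, p, M = 80, by = 1 / 2880)
  sched <- exogenous_schedule(M = 80)
  i <- 1500
  h <- 1 / 2880
  for (v in c("G", "I", "beta", "beta_IN")) {
    fd <- unname((out[i + 1, v] - out[i - 1, v]) / (2 * h))
    an <- kpd_rhs(out[i, c("G", "I", "beta", "beta_IN", "c")],
                  out[i, "time"], p, sched, adaptation_policy())[[v]]
    expect_equal(fd, an, tolerance = 1e-4)
  }
})

test_that("rhs rejects non-finite and negative states", {
  p <- preset_params("B")
  expect_error(
    kpd_rhs(c(G = NaN, I = 1, beta = 0.5, beta_IN = 0.1, c = p$c_max),
            0, p, exogenous_schedule(), adaptation_policy()),
    "integration-state")
  expect_error(
    kpd_rhs(c(G = -5, I = 1, beta = 0.5, beta_IN = 0.1, c = p$c_max),
            0, p, exogenous_schedule(), adaptation_policy()),
    "integration-state")
  expect_error(system_state(G = -1, I = 1, beta = 0.5, beta_IN = 0, c = 1),
               "non-negative")
})

test_that("dynamic adaptation follows the sign of the glucose error and
           respects the ceiling", {
  p <- preset_params("B")
  pol <- adaptation_policy("dynamic")
  mk <- function(G, csec) c(G = G, I = 5, beta = 0.4, beta_IN = 0.2, c = csec)
  d_hi <- kpd_rhs(mk(120, p$c_max / 2), 0, p, exogenous_schedule(), pol)
  d_lo <- kpd_rhs(mk(60, p$c_max / 2), 0, p, exogenous_schedule(), pol)
  d_eq <- kpd_rhs(mk(p$G_0, p$c_max / 2), 0, p, exogenous_schedule(), pol)
  expect_gt(d_hi[["c"]], 0)
  expect_lt(d_lo[["c"]], 0)
  expect_equal(d_eq[["c"]], 0)
  # clipped at the ceiling: no growth past c_max
  d_cap <- kpd_rhs(mk(120, p$c_max), 0, p, exogenous_schedule(), pol)
  expect_identical(d_cap[["c"]], 0)
})
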