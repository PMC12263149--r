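test_that("steady_beta matches its closed form and limits", {
  b <- preset_params("B")
  expect_equal(steady_beta(0, b), b$beta_TOT)
  # negligible inactivation leaves the pool fully active at any glucose
  p_noin <- update_parameters(b, k_IN = 1e-12)
  expect_equal(steady_beta(500, p_noin), b$beta_TOT, tolerance = 1e-9)
  # at the calibrated operating point: beta_TOT / (1 + 1775 g(110))
  rho <- b$k_IN / b$k_RE
  expect_equal(rho, 1775)
  expect_equal(steady_beta(110, b),
               b$beta_TOT / (1 + rho * inactivation_fraction(110, b$K_g)))
  expect_equal(steady_beta(110, b), b$beta_TOT / 2.288, tolerance = 1e-3)
  # decreasing in G
  expect_true(all(diff(steady_beta(seq(0, 1000, 10), b)) < 0))
})

test_that("companion-matrix roots recover a known factorization", {
  # (G - 50)(G - 200)(G - 800)(G^2 + 1), scaled
  co <- 1
  for (r in c(50, 200, 800)) co <- kpdsim:::polymul(co, c(-r, 1))
  co <- kpdsim:::polymul(co, c(1, 0, 1)) * 3.7
  roots <- companion_roots(co)
  real <- sort(Re(roots)[abs(Im(roots)) < 1e-8 * pmax(abs(roots), 1)])
  expect_equal(real, c(50, 200, 800), tolerance = 1e-9)
  expect_error(companion_roots(c(0, 0)), "degenerate")
})

test_that("with no beta cells the glucose balance has its analytic root", {
  p <- canonical_parameters()
  # no insulin: production m_0/I_0 balances S_E G at G = m_0/(S_E I_0)
  expect_equal(solve_glucose(0, p), p$m_0 / (p$S_E * p$I_0), tolerance = 1e-9)
  expect_equal(solve_glucose(0, p), 1200, tolerance = 1e-6)
  expect_error(fixed_point_polynomial(-0.1, p), "non-negative")
})

test_that("the cleared quintic vanishes at every verified glucose root", {
  b <- preset_params("B")
  set.seed(7)
  for (i in 1:20) {
    beta <- runif(1, 0, 1)
    M <- runif(1, 0, 300)
    F_I <- runif(1, 0, 1000)
    poly <- fixed_point_polynomial(beta, b, M = M, F_I = F_I)
    roots <- solve_glucose(beta, b, M = M, F_I = F_I)
    expect_gte(length(roots), 1)
    for (G in roots) {
      # polynomial residual is zero relative to the coefficient scale
      expect_lt(abs(kpdsim:::polyeval(poly, G)),
                1e-7 * max(abs(poly)) * max(G, 1)^5)
      # and the un-cleared balance residual is zero too
      expect_lt(abs(kpdsim:::glucose_balance_residual(G, beta, b, M, F_I)),
                1e-7 * kpdsim:::glucose_balance_scale(G, beta, b, M, F_I))
    }
  }
})

test_that("with negligible insulin action the roots match dense bisection", {
  # S_I -> 0 reduces the balance to production + intake = S_E G
  p <- update_parameters(canonical_parameters(), S_I = 1e-12)
  for (beta in c(0.2, 0.8)) {
    roots <- solve_glucose(beta, p, M = 50)
    resid <- function(G) {
      I <- beta * p$c_max * secretion_fraction(G, p$K_f) / p$gamma
      p$m_0 / (p$I_0 + I) + 50 - G * p$S_E
    }
    Gs <- seq(0.5, 5000, by = 0.5)
    rs <- vapply(Gs, resid, numeric(1))
    idx <- which(diff(sign(rs)) != 0)
    brute <- vapply(idx, function(i) {
      uniroot(resid, c(Gs[i], Gs[i + 1]), tol = 1e-10)$root
    }, numeric(1))
    expect_equal(sort(roots), sort(brute), tolerance = 1e-7)
  }
})

test_that("fixed-point counts match the virtual-patient phenotypes", {
  fpA <- preset_fp("A")
  expect_identical(nrow(fpA), 1L)
  expect_identical(fpA$stability, "stable")
  expect_identical(attr(fpA, "regime"), "monostable_healthy")

  fpB <- preset_fp("B")
  expect_identical(nrow(fpB), 3L)
  expect_identical(sum(fpB$stability == "stable"), 2L)
  expect_identical(attr(fpB, "regime"), "bistable")
  # unstable point sits between the two stable ones in G and beta
  expect_identical(fpB$stability, c("stable", "unstable", "stable"))
  expect_identical(fpB$branch,
                   c("healthy_high_beta", "intermediate",
                     "hyperglycemic_low_beta"))
  # intake past the saddle-node leaves only the hyperglycemic state
  fp_hi <- find_fixed_points(preset_params("B"), M = 500)
  expect_identical(attr(fp_hi, "regime"), "monostable_hyperglycemic")
  expect_identical(sum(fp_hi$stability == "stable"), 1L)
})

test_that("polynomial fixed points agree with the dense sign-scan oracle
           across random virtual patients", {
  worst <- 0
  for (s in 1:25) {
    p <- sample_virtual_patient(s, 0.2)
    fp <- find_fixed_points(p, check_jacobian = FALSE)
    brute <- brute_fixed_points(p)
    expect_identical(nrow(fp), length(brute))
    worst <- max(worst, max(abs(sort(fp$G) - sort(brute))))
    # stability labels alternate along the glucose axis
    if (nrow(fp) > 1) {
      expect_true(all(fp$stability[-1] != fp$stability[-nrow(fp)]))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the reduced slow flow vanishes at fixed points and changes sign
           across the unstable threshold", {
  b <- preset_params("B")
  fp <- preset_fp("B")
  for (i in seq_len(nrow(fp))) {
    expect_lt(abs(reduced_flow(fp$beta[i], b)), 1e-8)
  }
  bu <- fp$beta[fp$stability == "unstable"]
  # above the threshold the pool recovers toward the healthy state,
  # below it decays toward the hyperglycemic state
  expect_gt(reduced_flow(bu * 1.05, b), 0)
  expect_lt(reduced_flow(bu * 0.95, b), 0)
  # with the whole pool active at a glucose where inactivation acts,
  # the flow cannot be positive
  expect_lte(reduced_flow(b$beta_TOT, b), 0)
})

test_that("the inactivation/reactivation ratio opens and closes a bistable
           window", {
  a <- preset_params("A")
  sc <- scan_1d(a, "k_ratio", 10^seq(0, 4, length.out = 65))
  d <- tidy(sc)
  per_value <- dplyr::distinct(d, value, regime)
  runs <- rle(per_value$regime)
  expect_identical(runs$values,
                   c("monostable_healthy", "bistable",
                     "monostable_hyperglycemic"))
  bif <- attr(sc, "bifurcations")
  expect_identical(nrow(bif), 2L)
  # bisection postcondition: regimes differ just across each boundary
  for (i in seq_len(nrow(bif))) {
    lo <- scan_1d(a, "k_ratio", bif$value[i] * c(0.999, 1.001))
    expect_identical(dplyr::n_distinct(tidy(lo)$regime), 2L)
  }
})

test_that("insulin infusion pushes the KPD patient past a bifurcation into
           the healthy basin", {
  b <- preset_params("B")
  sc <- scan_1d(b, "F_I", seq(0, 2000, length.out = 21))
  d <- dplyr::distinct(tidy(sc), value, regime)
  expect_identical(d$regime[d$value == 0], "bistable")
  expect_identical(d$regime[nrow(d)], "monostable_healthy")
  bif <- attr(sc, "bifurcations")
  expect_gt(min(bif$value), 0)
})

test_that("scan grids are validated", {
  b <- preset_params("B")
  expect_error(scan_1d(b, "S_I", c(-1, 1)), "positive-parameter")
  expect_error(scan_1d(b, "M", c(0, 10, 5)), "monotone")
})

test_that("the phase diagram separates the KPD-susceptible and
           conventional phenotypes", {
  grid <- seq(0.5, 1.5, length.out = 5)
  pdA <- phase_diagram(preset_params("A"), grid, grid)
  expect_true(all(pdA$hatch == "no_hatch"))

  pdB <- phase_diagram(preset_params("B"), grid, grid)
  at11 <- pdB[pdB$S_I_rel == 1 & pdB$beta_TOT_rel == 1, ]
  expect_identical(at11$hatch, "single_hatch")
  # loss of beta-cell reserve produces total insulin dependence
  expect_gt(sum(pdB$hatch == "double_hatch"), 0)

  # ample insulin sensitivity: adaptation lowers secretion until fasting
  # glucose sits exactly at the 80 mg/dL target, with a single healthy state
  pd_hi <- phase_diagram(preset_params("B"), S_I_grid = 5, beta_TOT_grid = 1)
  expect_identical(pd_hi$hatch, "no_hatch")
  expect_equal(pd_hi$fasting_G, 80, tolerance = 1e-6)
  expect_lt(pd_hi$c_adapted, preset_params("B")$c_max)
})
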