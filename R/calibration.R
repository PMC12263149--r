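#' Canonical reference parameter set
#'
#' The shared constants of the virtual-patient presets. The fast-subsystem
#' constants follow the established beta-cell mass/insulin/glucose
#' modelling literature: glucose effectiveness `S_E = 1.44`/day, insulin
#' sensitivity `S_I = 0.72` mL/uU/day, insulin clearance `gamma = 432`/day,
#' secretion half-max `K_f = sqrt(20000) ~ 141.4` mg/dL, and a reference
#' hepatic glucose production `R_ref = 864` mg/dL/day. Hepatic production
#' is insulin-suppressed here, `m_0/(I_0 + I)` with `I_0 = 5` uU/mL and
#' `m_0 = 2 I_0 R_ref` so that production equals `R_ref` at `I = I_0`.
#' Two self-checks pin the operating point: steady-state fasting insulin at
#' `G = 110` mg/dL computes to about 7 uU/mL, and fasting hepatic
#' production there sits roughly 15% below `R_ref`.
#'
#' The inactivation half-max is [derive_K_g()]; the death half-max
#' `K_h = 200` mg/dL places permanent glucotoxicity in the severe
#' hyperglycemic range. Glucotoxicity rates default to the KPD-susceptible
#' phenotype (preset B); see [kpd_preset()].
#'
#' @return A [model_parameters()] object.
#' @export
#' @examples
#' p <- canonical_parameters()
#' hepatic_production(p$I_0, p)   # equals R_ref = 864
canonical_parameters <- function() {
  R_ref <- 864
  I_0 <- 5
  model_parameters(
    m_0 = 2 * I_0 * R_ref,
    I_0 = I_0,
    S_E = 1.44,
    S_I = 0.72,
    gamma = 432,
    K_f = sqrt(20000),
    K_g = derive_K_g(),
    K_h = 200,
    k_IN = 71,
    k_RE = 0.04,
    k_D = 1e-3,
    beta_TOT = 1,
    c_max = 1.85e4,   # placeholder scale; presets carry the calibrated value
    G_0 = 80
  )
}

#' Reference hepatic glucose production
#'
#' `R_ref = m_0 / (2 I_0)`: the production rate at `I = I_0`, used as the
#' fixed reference for meal scaling (instantaneous production is
#' state-dependent). 864 mg/dL/day for the canonical constants.
#'
#' @param params A [model_parameters()] object.
#' @return Glucose flux, mg/dL/day.
#' @export
reference_production <- function(params = canonical_parameters()) {
  params$m_0 / (2 * params$I_0)
}

#' Inactivation half-max from the physiological anchor
#'
#' The reversible-inactivation response is anchored by its value at
#' physiological glucose: `g(100 mg/dL) = 0.0006`. With Hill exponent 2
#' this inverts uniquely to `K_g = 100 sqrt((1 - 0.0006)/0.0006)`,
#' about 4081.3 mg/dL.
#'
#' @param g_at_100 Anchor value of `g` at 100 mg/dL.
#' @return Half-max constant, mg/dL.
#' @export
derive_K_g <- function(g_at_100 = 6e-4) {
  100 * sqrt((1 - g_at_100) / g_at_100)
}

#' Steady-state insulin maintaining a given fasting glucose
#'
#' At `dG/dt = 0` with no intake, the glucose balance reduces to a
#' quadratic in insulin:
#' `S_I G I^2 + (S_E G + S_I G I_0) I + S_E G I_0 - m_0 = 0`.
#' The positive root is the plasma insulin level that holds fasting
#' glucose at `G`. It is strictly decreasing in `G` and reaches zero at
#' the zero-insulin balance point `G = m_0/(S_E I_0)`.
#'
#' @param G_target Fasting glucose to maintain, mg/dL.
#' @param params A [model_parameters()] object.
#' @return Insulin concentration, uU/mL.
#' @export
#' @examples
#' insulin_for_target(110, canonical_parameters())  # ~ 7.05 uU/mL
insulin_for_target <- function(G_target, params) {
  if (!is.numeric(G_target) || any(G_target <= 0)) {
    abort("G_target must be positive")
  }
  vapply(G_target, function(G) {
    a <- params$S_I * G
    b <- params$S_E * G + params$S_I * G * params$I_0
    cc <- params$S_E * G * params$I_0 - params$m_0
    disc <- b^2 - 4 * a * cc
    if (disc < 0) abort("target infeasible: no real insulin level maintains G_target")
    root <- (-b + sqrt(disc)) / (2 * a)
    if (root < -1e-12) {
      abort("target infeasible: no non-negative insulin level maintains G_target")
    }
    max(root, 0)
  }, numeric(1))
}

#' Calibrate the secretion scale to a target healthy fasting glucose
#'
#' Solves the two steady-state conditions (glucose balance and the
#' equilibrated inactivation cycle) for the secretion scale that places the
#' healthy fasting fixed point at `target_G` with zero intake and zero
#' infusion. With `beta_TOT` normalized to 1 this returns `c_max`:
#' `c_max = gamma I*(target_G) (1 + (k_IN/k_RE) g(target_G)) /
#' (beta_TOT f(target_G))`.
#'
#' @param params A [model_parameters()] object carrying the preset's rate
#'   constants (`k_IN`, `k_RE`, `beta_TOT`).
#' @param target_G Fasting glucose of the healthy fixed point, mg/dL.
#' @return The calibrated `c_max` (uU/mL/day).
#' @export
calibrate_secretion <- function(params, target_G = 110) {
  I_star <- insulin_for_target(target_G, params)
  f <- secretion_fraction(target_G, params$K_f)
  rho <- params$k_IN / params$k_RE
  g <- inactivation_fraction(target_G, params$K_g)
  c_max <- params$gamma * I_star * (1 + rho * g) / (params$beta_TOT * f)
  if (!is.finite(c_max) || c_max <= 0) {
    abort("infeasible-target error: no positive secretion scale achieves target_G")
  }
  c_max
}

preset_rate_table <- function() {
  tibble::tibble(
    label = c("A", "B", "C", "D"),
    phenotype = c("non-KPD (low inactivation)",
                  "KPD, remits",
                  "KPD, slow reactivation",
                  "KPD, permanent loss"),
    k_IN = c(4.8, 71, 71, 71),
    k_RE = c(0.04, 0.04, 0.028, 0.028),
    k_D = c(1e-3, 1e-3, 1e-3, 0.07)
  )
}

#' Virtual-patient presets
#'
#' Four phenotypes distinguished only by their glucotoxicity rates, each
#' calibrated (via [calibrate_secretion()]) so that the healthy fasting
#' fixed point sits at `G = 110` mg/dL with the reversible cycle
#' equilibrated:
#'
#' * `A`: low inactivation rate (`k_IN = 4.8`/day) -- monostable, no
#'   KPD-like switching.
#' * `B`: high inactivation rate (`k_IN = 71`/day) -- bistable; a
#'   high-sugar episode switches it to persistent hyperglycemia and an
#'   insulin course can restore it.
#' * `C`: as `B` with slower reactivation (`k_RE = 0.028`/day) -- remits,
#'   but needs a longer insulin course.
#' * `D`: as `C` with fast permanent death (`k_D = 0.07`/day) -- fails to
#'   achieve insulin-free remission.
#'
#' @param label One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param K_h Optional override of the death half-max, mg/dL (the preset-D
#'   phenotype is robust across 100-250 mg/dL).
#' @return For `kpd_preset()`: a list with elements `label`, `phenotype`,
#'   and `params` (a [model_parameters()] object). For `kpd_presets()`: a
#'   tibble with one row per preset and a `params` list-column.
#' @export
#' @examples
#' b <- kpd_preset("B")
#' b$params$k_IN / b$params$k_RE   # 1775
kpd_preset <- function(label = c("A", "B", "C", "D"), K_h = NULL) {
  label <- match.arg(label)
  tab <- preset_rate_table()
  row <- tab[tab$label == label, ]
  p <- update_parameters(canonical_parameters(),
                         k_IN = row$k_IN, k_RE = row$k_RE, k_D = row$k_D)
  if (!is.null(K_h)) p <- update_parameters(p, K_h = K_h)
  p <- update_parameters(p, c_max = calibrate_secretion(p, target_G = 110))
  list(label = label, phenotype = row$phenotype, params = p)
}

#' @rdname kpd_preset
#' @export
kpd_presets <- function() {
  tab <- preset_rate_table()
  tab$params <- purrr::map(tab$label, function(l) kpd_preset(l)$params)
  tab
}

#' Sample a virtual patient by perturbing the canonical parameters
#'
#' Test plumbing for property-based checks: draws an independent log-normal
#' multiplier (median 1, coefficient of variation `dispersion`) for every
#' rate constant, rejecting draws that violate the parameter invariants
#' (notably `K_g > K_f`). Deterministic given `seed`; `dispersion = 0`
#' returns the base set exactly.
#'
#' @param seed Integer RNG seed.
#' @param dispersion Coefficient of variation of the log-normal
#'   multipliers.
#' @param base Parameter set to perturb.
#' @return A [model_parameters()] object.
#' @export
sample_virtual_patient <- function(seed, dispersion = 0.2,
                                   base = kpd_preset("B")$params) {
  if (dispersion < 0) abort("dispersion must be non-negative")
  if (dispersion == 0) return(base)
  fields <- setdiff(parameter_fields(), "G_0")
  sdlog <- sqrt(log(1 + dispersion^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  for (i in 1:100) {
    mult <- stats::rlnorm(length(fields), meanlog = 0, sdlog = sdlog)
    cand <- unclass(base)
    cand[fields] <- purrr::map2(cand[fields], mult, `*`)
    ok <- tryCatch({
      validate_parameters(cand)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(validate_parameters(cand))
  }
  abort("rejection sampling failed to produce a valid parameter set")
}

#' Typical daily glucose intake reference
#'
#' A standard whole-body glucose flux of 2 mg per kg per minute at 70 kg
#' body weight corresponds to about 201.6 g of glucose per day -- the scale
#' against which the high-sugar-consumption condition (roughly 70% of daily
#' hepatic production) corresponds to a few cans of soda per day.
#'
#' @param body_weight_kg Body weight, kg.
#' @param flux_mg_per_kg_min Whole-body glucose flux, mg/kg/min.
#' @return Grams of glucose per day.
#' @export
daily_glucose_reference <- function(body_weight_kg = 70,
                                    flux_mg_per_kg_min = 2) {
  flux_mg_per_kg_min * body_weight_kg * 1440 / 1000
}

#' Check the shipped preset config files against the calibration routines
#'
#' The presets ship as JSON configs under `inst/extdata/`; this verifies
#' they match what [kpd_preset()] computes, failing on drift.
#'
#' @param dir Directory holding `preset_A.json` ... `preset_D.json`;
#'   defaults to the installed package copies.
#' @param tol Relative tolerance for numeric comparison.
#' @return Invisibly `TRUE`; aborts on drift.
#' @export
check_preset_files <- function(dir = system.file("extdata", package = "kpdsim"),
                               tol = 1e-8) {
  for (label in c("A", "B", "C", "D")) {
    path <- file.path(dir, paste0("preset_", label, ".json"))
    shipped <- unlist(unclass(read_parameters(path)))
    computed <- unlist(unclass(kpd_preset(label)$params))
    rel <- abs(shipped - computed) / pmax(abs(computed), 1e-12)
    if (any(rel > tol)) {
      bad <- names(rel)[rel > tol]
      abort(paste0("preset ", label, " config drifted from calibration: ",
                   paste(bad, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Regenerate the preset config files
#'
#' @param dir Output directory.
#' @return Invisibly the written paths.
#' @export
write_preset_files <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (label in c("A", "B", "C", "D")) {
    path <- file.path(dir, paste0("preset_", label, ".json"))
    write_parameters(kpd_preset(label)$params, path)
    paths <- c(paths, path)
  }
  write_parameters(canonical_parameters(), file.path(dir, "canonical.json"))
  invisible(c(paths, file.path(dir, "canonical.json")))
}
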