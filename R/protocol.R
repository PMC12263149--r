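#' Active beta-cell fraction under glucose clamped at the treatment floor
#'
#' With fasting glucose held at `G_min` (and permanent death neglected),
#' the inactivation cycle becomes linear and solves in closed form:
#' \deqn{\beta(t)/\beta_{TOT} = e^{-(k_{RE}+k_{IN} g(G_{min})) t}
#'   (\beta(0)/\beta_{TOT} - \beta_\infty/\beta_{TOT}) +
#'   \beta_\infty/\beta_{TOT},}
#' with asymptote `beta_inf = beta_TOT k_RE / (k_RE + k_IN g(G_min))`
#' (equal to [steady_beta()] at `G_min`).
#'
#' @param t Time since treatment start, days (vectorized).
#' @param G_min Glucose floor during treatment, mg/dL.
#' @param beta_start Active fraction at treatment start.
#' @param params A [model_parameters()] object.
#' @return Active beta-cell fraction at `t`.
#' @export
beta_trajectory <- function(t, G_min, beta_start, params) {
  rate <- recovery_rate(G_min, params)
  beta_inf <- steady_beta(G_min, params)
  exp(-rate * t) * (beta_start - beta_inf) + beta_inf
}

recovery_rate <- function(G_min, params) {
  params$k_RE + params$k_IN * inactivation_fraction(G_min, params$K_g)
}

#' Insulin dose schedule holding fasting glucose at a floor
#'
#' Given the clamped-glucose recovery of the active fraction
#' ([beta_trajectory()]) and the constant plasma insulin `I*` that
#' maintains `G_min` ([insulin_for_target()]), the infusion that delivers
#' the balance between `gamma I*` and endogenous secretion is
#' `F_I(t) = gamma I* - beta(t) c_max f(G_min)`, floored at zero. The
#' schedule starts high and decays exponentially as secretion recovers
#' (the log of the gap to its asymptote is affine in `t`); if asymptotic
#' endogenous secretion exceeds `gamma I*`, the dose reaches zero at a
#' finite floor time, after which endogenous secretion alone suffices.
#'
#' @param t Time since treatment start, days (vectorized).
#' @inheritParams beta_trajectory
#' @return Infusion rate `F_I`, uU/mL/day.
#' @export
dose_schedule <- function(t, G_min, beta_start, params) {
  I_star <- insulin_for_target(G_min, params)
  f_min <- secretion_fraction(G_min, params$K_f)
  pmax(0, params$gamma * I_star -
         beta_trajectory(t, G_min, beta_start, params) * params$c_max * f_min)
}

dose_floor_time <- function(G_min, beta_start, params) {
  I_star <- insulin_for_target(G_min, params)
  f_min <- secretion_fraction(G_min, params$K_f)
  beta_need <- params$gamma * I_star / (params$c_max * f_min)
  beta_inf <- steady_beta(G_min, params)
  if (beta_need <= beta_start) return(0)
  if (beta_need >= beta_inf) return(Inf)
  rate <- recovery_rate(G_min, params)
  log((beta_inf - beta_start) / (beta_inf - beta_need)) / rate
}

#' Time to reach remission under the optimal protocol
#'
#' Inverts the clamped-glucose closed form for the time at which the
#' active fraction reaches the remission target `beta_target` (by default
#' the untreated healthy-fixed-point beta). Because an exponential only
#' approaches its asymptote, the reach point is taken 1% of the
#' `beta_target - beta_start` gap short of the target (`band`). Returns
#' `Inf` whenever the treated asymptote `beta_inf(G_min)` does not exceed
#' `beta_target` -- which is exactly the case `G_min >=` the untreated
#' healthy fasting glucose, so targeting at or above the fixed point never
#' produces remission.
#'
#' @inheritParams beta_trajectory
#' @param beta_target Remission target for the active fraction; defaults
#'   to the healthy-fixed-point beta of `params`.
#' @param band Fraction of the start-to-target gap accepted as "reached".
#' @return Days to remission (possibly `Inf`).
#' @export
#' @examples
#' p <- kpd_preset("B")$params
#' time_to_remission(100, beta_start = 0.05, params = p)
#' time_to_remission(110, beta_start = 0.05, params = p)  # Inf
time_to_remission <- function(G_min, beta_start, params,
                              beta_target = NULL, band = 0.01) {
  if (is.null(beta_target)) {
    fp <- find_fixed_points(params, check_jacobian = FALSE)
    st <- fp[fp$stability == "stable", ]
    beta_target <- max(st$beta)
  }
  if (beta_start >= beta_target) return(0)
  beta_inf <- steady_beta(G_min, params)
  if (beta_inf <= beta_target) return(Inf)
  beta_reach <- beta_target - band * (beta_target - beta_start)
  rate <- recovery_rate(G_min, params)
  log((beta_inf - beta_start) / (beta_inf - beta_reach)) / rate
}

#' Optimal insulin treatment protocol under a fasting-glucose floor
#'
#' The fastest safe remission course: no sugar intake, and insulin
#' continuously titrated so fasting glucose sits exactly at the floor
#' `G_min` chosen to avoid hypoglycemia. Combines the constant maintenance
#' insulin `I*` ([insulin_for_target()]), the closed-form recovery of the
#' active fraction ([beta_trajectory()]), the decaying dose schedule
#' ([dose_schedule()]), and the remission time ([time_to_remission()]).
#'
#' @param G_min Fasting-glucose floor, mg/dL.
#' @param beta_start Active fraction at treatment start; defaults to the
#'   hyperglycemic-fixed-point beta of `params` (a patient presenting in
#'   crisis).
#' @param params A [model_parameters()] object.
#' @param horizon Days covered by the tabulated schedule.
#' @param n Number of schedule rows.
#' @return An object of class `kpd_protocol`: list with `G_min`,
#'   `beta_start`, `I_star`, `time_to_remission`, `dose_floor_time`,
#'   `schedule` (tibble `t`, `beta`, `F_I`), and `params`.
#' @export
#' @examples
#' p <- kpd_preset("B")$params
#' pr <- optimal_protocol(90, params = p)
#' pr$I_star
optimal_protocol <- function(G_min, beta_start = NULL, params,
                             horizon = 120, n = 241) {
  if (G_min <= 0) abort("G_min must be positive")
  if (is.null(beta_start)) {
    fp <- find_fixed_points(params, check_jacobian = FALSE)
    st <- fp[fp$stability == "stable", ]
    beta_start <- min(st$beta)
  }
  if (beta_start < 0 || beta_start > params$beta_TOT) {
    abort("beta_start must lie in [0, beta_TOT]")
  }
  tgrid <- seq(0, horizon, length.out = n)
  schedule <- tibble::tibble(
    t = tgrid,
    beta = beta_trajectory(tgrid, G_min, beta_start, params),
    F_I = dose_schedule(tgrid, G_min, beta_start, params)
  )
  structure(list(
    G_min = G_min, beta_start = beta_start,
    I_star = insulin_for_target(G_min, params),
    time_to_remission = time_to_remission(G_min, beta_start, params),
    dose_floor_time = dose_floor_time(G_min, beta_start, params),
    schedule = schedule, params = params
  ), class = "kpd_protocol")
}

#' Remission-time curve over a set of glucose targets
#'
#' @param G_min Vector of fasting-glucose floors, mg/dL.
#' @inheritParams optimal_protocol
#' @return Tibble with columns `G_min`, `time_to_remission`, `I_star`.
#' @export
remission_curve <- function(G_min = c(85, 90, 95, 100), beta_start = NULL,
                            params) {
  if (is.null(beta_start)) {
    fp <- find_fixed_points(params, check_jacobian = FALSE)
    st <- fp[fp$stability == "stable", ]
    beta_start <- min(st$beta)
  }
  fp <- find_fixed_points(params, check_jacobian = FALSE)
  st <- fp[fp$stability == "stable", ]
  beta_target <- max(st$beta)
  tibble::tibble(
    G_min = G_min,
    time_to_remission = vapply(
      G_min, time_to_remission, numeric(1),
      beta_start = beta_start, params = params, beta_target = beta_target),
    I_star = insulin_for_target(G_min, params)
  )
}

#' @export
print.kpd_protocol <- function(x, ...) {
  cat("<kpd_protocol>  G_min:", x$G_min, "mg/dL\n")
  cat("maintenance insulin I*:", format(x$I_star, digits = 4), "uU/mL\n")
  cat("time to remission:", format(x$time_to_remission, digits = 4), "days\n")
  cat("dose reaches zero at:", format(x$dose_floor_time, digits = 4), "days\n")
  invisible(x)
}
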