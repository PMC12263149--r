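#' System state at a time point
#'
#' A named numeric vector of the dynamical variables: plasma glucose `G`
#' (mg/dL), plasma insulin `I` (uU/mL), active beta-cell fraction `beta`,
#' inactive fraction `beta_IN`, and per-cell secretion capacity `c`
#' (uU/mL/day).
#'
#' @param G,I,beta,beta_IN Non-negative state components.
#' @param c Per-cell secretion capacity, in `(0, c_max]` of the parameter
#'   set the state is used with.
#' @param t Time, days (carried as an attribute on trajectories, not here).
#' @return Named numeric vector with components `G`, `I`, `beta`,
#'   `beta_IN`, `c`.
#' @export
system_state <- function(G, I, beta, beta_IN, c, t = 0) {
  y <- c(G = G, I = I, beta = beta, beta_IN = beta_IN, c = c)
  if (any(!is.finite(y))) abort("state components must be finite")
  if (any(y[c("G", "I", "beta", "beta_IN")] < 0)) {
    abort("G, I, beta and beta_IN must be non-negative")
  }
  if (c <= 0) abort("per-cell secretion c must be positive")
  y
}

#' Exogenous meal and insulin schedule
#'
#' Wraps the two time-dependent inputs of the model: the glucose intake
#' flux `M(t)` (meals, mg/dL/day) and the exogenous insulin infusion
#' `F_I(t)` (uU/mL/day). Each may be a single non-negative constant or a
#' function of time returning a non-negative flux. `F_I` may additionally
#' accept the current state as a second argument, which is how titrated
#' (state-feedback) insulin dosing is expressed.
#'
#' @param M Glucose intake flux: constant or `function(t)`.
#' @param F_I Insulin infusion flux: constant, `function(t)`, or
#'   `function(t, state)`.
#' @return An object of class `kpd_schedule`.
#' @export
exogenous_schedule <- function(M = 0, F_I = 0) {
  structure(list(M = as_flux_fn(M, "M"), F_I = as_flux_fn(F_I, "F_I")),
            class = "kpd_schedule")
}

as_flux_fn <- function(x, what) {
  if (is.numeric(x) && length(x) == 1) {
    if (!is.finite(x) || x < 0) {
      abort(paste0(what, " must be a non-negative flux"))
    }
    val <- x
    return(function(t, state = NULL) val)
  }
  if (is.function(x)) {
    if (length(formals(x)) >= 2) return(x)
    return(function(t, state = NULL) x(t))
  }
  abort(paste0(what, " must be a constant or a function of time"))
}

#' Time derivatives of the full model
#'
#' The right-hand side of the coupled system: fast glucose-insulin
#' feedback, reversible beta-cell inactivation/reactivation, permanent
#' beta-cell death, and (optionally) slow adaptation of the per-cell
#' secretion capacity:
#'
#' \deqn{dG/dt = M(t) + m_0/(I_0 + I) - (S_E + S_I I) G}
#' \deqn{dI/dt = \beta c f(G) - \gamma I + F_I(t)}
#' \deqn{d\beta/dt = -(k_{IN} g(G) + k_D h(G)) \beta + k_{RE} \beta_{IN}}
#' \deqn{d\beta_{IN}/dt = -(k_{RE} + k_D h(G)) \beta_{IN} + k_{IN} g(G) \beta}
#'
#' `dc/dt` is zero in the frozen and quasi-static modes and
#' `k_a (G - G_0)` (clipped to keep `c` in `(0, c_max]`) in dynamic mode.
#' With `k_D = 0` the total pool `beta + beta_IN` is exactly conserved.
#'
#' @param state Named state vector from [system_state()].
#' @param t Time, days.
#' @param params A [model_parameters()] object.
#' @param schedule An [exogenous_schedule()].
#' @param adaptation An [adaptation_policy()].
#' @return Named numeric vector of derivatives (`G`, `I`, `beta`,
#'   `beta_IN`, `c`), per day.
#' @export
kpd_rhs <- function(state, t = 0, params,
                    schedule = exogenous_schedule(),
                    adaptation = adaptation_policy()) {
  if (any(!is.finite(state))) {
    abort("integration-state error: non-finite state component")
  }
  if (any(state[c("G", "I", "beta", "beta_IN")] < -1e-8)) {
    abort("integration-state error: negative state component")
  }
  G <- max(state[["G"]], 0)
  I <- max(state[["I"]], 0)
  beta <- max(state[["beta"]], 0)
  beta_IN <- max(state[["beta_IN"]], 0)
  csec <- state[["c"]]

  f <- secretion_fraction(G, params$K_f)
  g <- inactivation_fraction(G, params$K_g)
  h <- death_fraction(G, params$K_h)
  M <- schedule$M(t)
  F_I <- schedule$F_I(t, state)

  dG <- M + params$m_0 / (params$I_0 + I) - (params$S_E + params$S_I * I) * G
  dI <- beta * csec * f - params$gamma * I + F_I
  dbeta <- -(params$k_IN * g + params$k_D * h) * beta + params$k_RE * beta_IN
  dbeta_IN <- -(params$k_RE + params$k_D * h) * beta_IN + params$k_IN * g * beta

  dc <- 0
  if (adaptation$mode == "dynamic") {
    k_a <- adaptation$k_a %||% default_k_a(params)
    G_f <- adaptation$G_f %||% G
    dc <- k_a * (G_f - params$G_0)
    # clip at the ceiling and at zero
    if ((csec >= params$c_max && dc > 0) || (csec <= 1e-12 * params$c_max && dc < 0)) {
      dc <- 0
    }
  }

  c(G = dG, I = dI, beta = dbeta, beta_IN = dbeta_IN, c = dc)
}

# deSolve-facing wrapper; returns list(derivatives)
rhs_desolve <- function(t, y, parms) {
  list(kpd_rhs(y, t, parms$params, parms$schedule, parms$adaptation))
}
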