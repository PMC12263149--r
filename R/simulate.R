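#' Meal glucose flux over a day
#'
#' Meals are three one-hour boxcar pulses (07:00, 12:00, 19:00) whose
#' daily integral is a fixed fraction of the reference hepatic production
#' `R_ref = m_0/(2 I_0)`: 3% under a `normal` plan, 70% under the
#' `high_sugar` plan (roughly three to four cans of soda per day on top of
#' normal eating), and zero when `fasting`. Only the daily total is
#' physiologically constrained; the boxcar shape is the simplest choice
#' compatible with breakpointed stiff integration.
#'
#' @param meal_plan One of `"normal"`, `"high_sugar"`, `"fasting"`.
#' @param t Time of day in days, in `[0, 1)` (vectorized; values outside
#'   are wrapped).
#' @param params A [model_parameters()] object (sets `R_ref`).
#' @return Glucose intake flux `M`, mg/dL/day.
#' @export
#' @examples
#' # daily integral: 3% of 864
#' integrate(function(t) meal_flux("normal", t), 0, 1)$value
meal_flux <- function(meal_plan = c("normal", "high_sugar", "fasting"), t,
                      params = canonical_parameters()) {
  meal_plan <- match.arg(meal_plan)
  frac <- switch(meal_plan, normal = 0.03, high_sugar = 0.70, fasting = 0)
  if (frac == 0) return(rep(0, length(t)))
  tod <- t %% 1
  amp <- frac * reference_production(params) / (3 / 24)
  in_meal <- (tod >= 7 / 24 & tod < 8 / 24) |
    (tod >= 12 / 24 & tod < 13 / 24) |
    (tod >= 19 / 24 & tod < 20 / 24)
  ifelse(in_meal, amp, 0)
}

meal_breaks <- function(meal_plan) {
  if (meal_plan == "fasting") return(numeric(0))
  c(7, 8, 12, 13, 19, 20) / 24
}

#' Treatment policies for scenario segments
#'
#' `treatment_none()` is no insulin. `treatment_constant()` is a constant
#' infusion `F_I`; when `F_I` is `NULL` it defaults, at integration time,
#' to 1.5 times the saddle-node infusion rate at which the hyperglycemic
#' branch vanishes (found by [scan_1d()]), i.e. a dose guaranteed to make
#' the healthy state the only attractor. `treatment_titrated()` adjusts the
#' infusion continuously so fasting glucose is held at the floor `G_min`:
#' `F_I = max(0, gamma I*(G_min) - beta c f(G_min))`, the state-feedback
#' form of the optimal protocol (see [optimal_protocol()]).
#'
#' @param F_I Constant infusion, uU/mL/day, or `NULL` for the automatic
#'   super-bifurcation dose.
#' @param G_min Fasting-glucose floor for titration, mg/dL.
#' @return A treatment policy object (list with a `type` field).
#' @export
treatment_none <- function() list(type = "none")

#' @rdname treatment_none
#' @export
treatment_constant <- function(F_I = NULL) {
  if (!is.null(F_I) && (!is.numeric(F_I) || F_I < 0)) {
    abort("F_I must be a non-negative dose")
  }
  list(type = "constant_dose", F_I = F_I)
}

#' @rdname treatment_none
#' @export
treatment_titrated <- function(G_min = 90) {
  if (!is.numeric(G_min) || G_min <= 0) abort("G_min must be positive")
  list(type = "titrated", G_min = G_min)
}

#' Build a clinical scenario
#'
#' A scenario is an ordered list of contiguous segments, each with a
#' duration (days), a meal plan, and a treatment policy. Treatment
#' segments may end early, once glucose is controlled (see
#' `until_controlled` in [scenario_segment()]).
#'
#' @param ... [scenario_segment()] objects, in order.
#' @param initial_state `"healthy_fixed_point"` (start at the high-beta
#'   fasting fixed point of the parameter set) or a [system_state()]
#'   vector.
#' @return An object of class `kpd_scenario`.
#' @export
#' @examples
#' sc <- kpd_scenario(
#'   scenario_segment(30, "normal"),
#'   scenario_segment(30, "high_sugar"),
#'   scenario_segment(60, "normal")
#' )
kpd_scenario <- function(..., initial_state = "healthy_fixed_point") {
  segments <- list(...)
  if (length(segments) == 0) abort("a scenario needs at least one segment")
  ok <- vapply(segments, function(s) inherits(s, "kpd_segment"), logical(1))
  if (!all(ok)) abort("segments must be built with scenario_segment()")
  structure(list(segments = segments, initial_state = initial_state),
            class = "kpd_scenario")
}

#' @rdname kpd_scenario
#' @param duration Segment length in days (positive integer; treatment
#'   segments with `until_controlled = TRUE` treat it as a maximum).
#' @param meal_plan Passed to [meal_flux()].
#' @param treatment A treatment policy ([treatment_none()],
#'   [treatment_constant()], [treatment_titrated()]).
#' @param until_controlled For treatment segments: stop once daily mean
#'   glucose has stayed below 110% of the healthy-fixed-point glucose for
#'   7 consecutive days (the operational reading of "treated until well
#'   controlled").
#' @export
scenario_segment <- function(duration,
                             meal_plan = c("normal", "high_sugar", "fasting"),
                             treatment = treatment_none(),
                             until_controlled = FALSE) {
  meal_plan <- match.arg(meal_plan)
  if (!is.numeric(duration) || duration <= 0) {
    abort("segment duration must be positive")
  }
  structure(list(duration = ceiling(duration), meal_plan = meal_plan,
                 treatment = treatment, until_controlled = until_controlled),
            class = "kpd_segment")
}

#' Solver configuration
#'
#' Defaults to the stiff fifth-order implicit Runge-Kutta method (Radau
#' IIA, as implemented in \pkg{deSolve}) with relative tolerance 1e-8 and
#' absolute tolerance 1e-10; meal and segment boundaries are handled as
#' hard integration breakpoints, and the dense output grid (`dt_out`, in
#' days) is what daily aggregates are computed from by trapezoidal
#' quadrature.
#'
#' @param method A \pkg{deSolve} method name (`"radau"` or `"lsoda"`).
#' @param rtol,atol Integration tolerances.
#' @param dt_out Dense output spacing, days.
#' @return A list of solver settings.
#' @export
solver_config <- function(method = "radau", rtol = 1e-8, atol = 1e-10,
                          dt_out = 1 / 288) {
  if (rtol <= 0 || atol <= 0 || dt_out <= 0) abort("tolerances must be positive")
  list(method = method, rtol = rtol, atol = atol, dt_out = dt_out)
}

healthy_initial_state <- function(params) {
  fp <- find_fixed_points(params, check_jacobian = FALSE)
  stable <- fp[fp$stability == "stable", ]
  i <- which.max(stable$beta)
  system_state(G = stable$G[i], I = stable$I[i], beta = stable$beta[i],
               beta_IN = params$beta_TOT - stable$beta[i], c = params$c_max)
}

segment_F_I_fn <- function(treatment, params) {
  if (treatment$type == "none") {
    return(function(t, state = NULL) 0)
  }
  if (treatment$type == "constant_dose") {
    dose <- treatment$F_I %||% (1.5 * saddle_node_F_I(params))
    return(function(t, state = NULL) dose)
  }
  # titrated: state feedback holding fasting glucose at the floor
  G_min <- treatment$G_min
  I_star <- insulin_for_target(G_min, params)
  f_min <- secretion_fraction(G_min, params$K_f)
  function(t, state = NULL) {
    max(0, params$gamma * I_star - state[["beta"]] * state[["c"]] * f_min)
  }
}

# infusion rate at which the hyperglycemic branch disappears (upper
# saddle-node of the F_I scan), used for the automatic constant dose
saddle_node_F_I <- function(params, F_I_max = 6000, n = 25) {
  sc <- scan_1d(params, "F_I", seq(0, F_I_max, length.out = n))
  bif <- attr(sc, "bifurcations")
  drop <- bif[bif$to < bif$from, ]
  if (nrow(drop) == 0) {
    abort("no saddle-node found in the infusion scan; raise F_I_max")
  }
  max(drop$value)
}

integrate_piece <- function(y0, t0, t1, params, schedule, adaptation, solver) {
  times <- unique(c(seq(t0, t1, by = solver$dt_out), t1))
  if (length(times) < 2) times <- c(t0, t1)
  parms <- list(params = params, schedule = schedule, adaptation = adaptation)
  sol <- if (solver$method == "radau") {
    deSolve::radau(y = y0, times = times, func = rhs_desolve, parms = parms,
                   rtol = solver$rtol, atol = solver$atol)
  } else {
    deSolve::ode(y = y0, times = times, func = rhs_desolve, parms = parms,
                 method = solver$method, rtol = solver$rtol, atol = solver$atol)
  }
  if (attr(sol, "istate")[1] < 0) {
    abort(paste0("integration failure near t = ", format(t0),
                 " (step-size collapse or tolerance failure)"))
  }
  m <- as.matrix(sol)
  if (any(m[, c("G", "I", "beta", "beta_IN")] < -1e-6)) {
    abort(paste0("integration failure: negative state near t = ", format(t0)))
  }
  m[, c("G", "I", "beta", "beta_IN")] <- pmax(m[, c("G", "I", "beta", "beta_IN")], 0)
  m
}

# integrate one day, splitting at meal boundaries; returns the dense matrix
integrate_day <- function(y0, day_start, meal_plan, F_I_fn, params,
                          adaptation, solver) {
  breaks <- sort(unique(c(0, meal_breaks(meal_plan), 1)))
  M_fn <- function(t, state = NULL) meal_flux(meal_plan, t, params)
  schedule <- structure(list(M = M_fn, F_I = F_I_fn), class = "kpd_schedule")
  pieces <- list()
  y <- y0
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- day_start + breaks[i]
    t1 <- day_start + breaks[i + 1]
    m <- integrate_piece(y, t0, t1, params, schedule, adaptation, solver)
    y <- m[nrow(m), c("G", "I", "beta", "beta_IN", "c")]
    pieces[[i]] <- if (i == 1) m else m[-1, , drop = FALSE]
  }
  do.call(rbind, pieces)
}

trapz_mean <- function(t, x) {
  if (length(t) < 2) return(x[1])
  dt <- diff(t)
  sum(dt * (head(x, -1) + tail(x, -1)) / 2) / (t[length(t)] - t[1])
}

#' Integrate a clinical scenario
#'
#' Runs the full model through the scenario's segments with the stiff
#' solver, meal pulses and segment boundaries treated as integration
#' breakpoints. Returns the dense trajectory, daily aggregates (trapezoidal
#' means plus daily extrema), and annotated clinical events from
#' [detect_events()].
#'
#' @param scenario A [kpd_scenario()].
#' @param params A [model_parameters()] object.
#' @param solver A [solver_config()].
#' @param adaptation An [adaptation_policy()]; the clinical scenarios run
#'   with the secretory capacity frozen at `c_max` (advanced prediabetes).
#' @param thresholds Event thresholds, passed to [detect_events()].
#' @return An object of class `kpd_sim`: list with tibbles `trajectory`
#'   (`t`, `G`, `I`, `beta`, `beta_IN`, `beta_tot`, `c`, `M`, `F_I`),
#'   `daily` (per-day aggregates and treatment flag), `events`, and
#'   `segments` (realized start/end days), plus `params`.
#' @export
simulate_scenario <- function(scenario, params,
                              solver = solver_config(),
                              adaptation = adaptation_policy(),
                              thresholds = event_thresholds()) {
  y <- if (identical(scenario$initial_state, "healthy_fixed_point")) {
    healthy_initial_state(params)
  } else {
    scenario$initial_state
  }
  fp0 <- find_fixed_points(params, check_jacobian = FALSE)
  st0 <- fp0[fp0$stability == "stable", ]
  healthy_G <- st0$G[which.max(st0$beta)]
  healthy_beta <- max(st0$beta)

  day <- 0L
  traj <- list()
  daily <- list()
  seg_rows <- list()

  for (si in seq_along(scenario$segments)) {
    seg <- scenario$segments[[si]]
    F_I_fn <- segment_F_I_fn(seg$treatment, params)
    on_insulin <- seg$treatment$type != "none"
    seg_start <- day
    controlled_streak <- 0L
    for (d in seq_len(seg$duration)) {
      m <- integrate_day(y, day, seg$meal_plan, F_I_fn, params,
                         adaptation, solver)
      y <- m[nrow(m), c("G", "I", "beta", "beta_IN", "c")]
      tt <- m[, "time"]
      keep <- if (length(traj) > 0) -1L else TRUE  # drop duplicated boundary row
      traj[[length(traj) + 1]] <- m[keep, , drop = FALSE]
      daily[[length(daily) + 1]] <- tibble::tibble(
        day = day + 1L,
        G_mean = trapz_mean(tt, m[, "G"]),
        G_min = min(m[, "G"]), G_max = max(m[, "G"]),
        I_mean = trapz_mean(tt, m[, "I"]),
        beta_mean = trapz_mean(tt, m[, "beta"]),
        beta_tot = m[nrow(m), "beta"] + m[nrow(m), "beta_IN"],
        on_insulin = on_insulin,
        segment = si, meal_plan = seg$meal_plan
      )
      day <- day + 1L
      if (on_insulin && seg$until_controlled) {
        if (seg$treatment$type == "titrated") {
          # glucose is clamped at the floor during titration, so "well
          # controlled" is judged on the recovered active fraction instead
          if (y[["beta"]] >= 0.99 * healthy_beta) break
        } else {
          if (daily[[length(daily)]]$G_mean < 1.1 * healthy_G) {
            controlled_streak <- controlled_streak + 1L
          } else {
            controlled_streak <- 0L
          }
          if (controlled_streak >= 7L) break
        }
      }
    }
    seg_rows[[si]] <- tibble::tibble(
      segment = si, meal_plan = seg$meal_plan,
      treatment = seg$treatment$type,
      start_day = seg_start, end_day = day
    )
  }

  tm <- do.call(rbind, traj)
  trajectory <- tibble::tibble(
    t = tm[, "time"], G = tm[, "G"], I = tm[, "I"],
    beta = tm[, "beta"], beta_IN = tm[, "beta_IN"],
    beta_tot = tm[, "beta"] + tm[, "beta_IN"], c = tm[, "c"]
  )
  segments <- dplyr::bind_rows(seg_rows)
  # exogenous fluxes reconstructed on the output grid
  trajectory$M <- flux_on_grid(trajectory$t, segments, scenario, params)
  trajectory$F_I <- infusion_on_grid(trajectory, segments, scenario, params)

  daily <- dplyr::bind_rows(daily)
  events <- detect_events(daily, segments, thresholds)

  structure(list(trajectory = trajectory, daily = daily, events = events,
                 segments = segments, params = params),
            class = "kpd_sim")
}

flux_on_grid <- function(t, segments, scenario, params) {
  M <- numeric(length(t))
  for (i in seq_len(nrow(segments))) {
    idx <- t >= segments$start_day[i] & t <= segments$end_day[i]
    M[idx] <- meal_flux(segments$meal_plan[i], t[idx], params)
  }
  M
}

infusion_on_grid <- function(trajectory, segments, scenario, params) {
  F_I <- numeric(nrow(trajectory))
  for (i in seq_len(nrow(segments))) {
    seg <- scenario$segments[[i]]
    if (seg$treatment$type == "none") next
    fn <- segment_F_I_fn(seg$treatment, params)
    idx <- which(trajectory$t >= segments$start_day[i] &
                   trajectory$t <= segments$end_day[i])
    for (j in idx) {
      st <- c(G = trajectory$G[j], I = trajectory$I[j],
              beta = trajectory$beta[j], beta_IN = trajectory$beta_IN[j],
              c = trajectory$c[j])
      F_I[j] <- fn(trajectory$t[j], st)
    }
  }
  F_I
}

#' Event detection thresholds
#'
#' The crisis threshold is a glucose-only proxy for a hyperglycemic
#' emergency (no ketone-body physiology is modelled); 130 mg/dL is the
#' conventional diabetes-control threshold.
#'
#' @param crisis_G Daily mean glucose defining crisis onset, mg/dL.
#' @param control_G Control threshold, mg/dL.
#' @param remission_days Consecutive controlled, insulin-free days after
#'   treatment that confirm remission.
#' @param relapse_days Consecutive uncontrolled days after remission that
#'   define relapse.
#' @return A list of thresholds.
#' @export
event_thresholds <- function(crisis_G = 300, control_G = 130,
                             remission_days = 14, relapse_days = 7) {
  list(crisis_G = crisis_G, control_G = control_G,
       remission_days = remission_days, relapse_days = relapse_days)
}

#' Annotate clinical events on a daily trajectory
#'
#' Scans daily aggregates for: `crisis_onset` (first day with mean glucose
#' above the crisis threshold), `treatment_start`/`treatment_end` (from the
#' segment timeline), `remission` (a treatment end followed by at least
#' `remission_days` consecutive insulin-free days below the control
#' threshold), and `relapse` (after a remission, the first day of a run of
#' `relapse_days` consecutive days above the control threshold).
#'
#' @param daily Daily aggregate tibble (as produced by
#'   [simulate_scenario()]), with columns `day`, `G_mean`, `on_insulin`.
#' @param segments Realized segment tibble (may be `NULL` when `daily`
#'   carries an `on_insulin` column describing treatment).
#' @param thresholds An [event_thresholds()] list.
#' @return Tibble with columns `t_day` and `kind`, ordered in time.
#' @export
detect_events <- function(daily, segments = NULL,
                          thresholds = event_thresholds()) {
  ev <- tibble::tibble(t_day = numeric(0), kind = character(0))
  crisis <- which(daily$G_mean > thresholds$crisis_G)
  if (length(crisis) > 0) {
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      t_day = daily$day[crisis[1]], kind = "crisis_onset"))
  }
  ins <- daily$on_insulin
  starts <- which(ins & !dplyr::lag(ins, default = FALSE))
  ends <- which(!ins & dplyr::lag(ins, default = FALSE)) - 1L
  if (length(ends) < length(starts)) ends <- c(ends, nrow(daily))
  for (k in seq_along(starts)) {
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      t_day = daily$day[starts[k]] - 1, kind = "treatment_start"))
    end_day <- daily$day[ends[k]]
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      t_day = end_day, kind = "treatment_end"))
    # remission: >= remission_days consecutive controlled insulin-free days
    after <- daily[daily$day > end_day & !daily$on_insulin, ]
    if (nrow(after) >= thresholds$remission_days) {
      controlled <- after$G_mean < thresholds$control_G
      run <- cumprod(controlled)  # leading run of controlled days
      if (sum(run) >= thresholds$remission_days) {
        ev <- dplyr::bind_rows(ev, tibble::tibble(
          t_day = end_day, kind = "remission"))
      }
    }
    # relapse: first sustained loss of control once insulin has stopped
    # (after the confirmed remission window if one exists)
    if (nrow(after) > 0) {
      rel <- relapse_day(after$G_mean > thresholds$control_G,
                         after$day, thresholds$relapse_days)
      if (!is.na(rel)) {
        ev <- dplyr::bind_rows(ev, tibble::tibble(
          t_day = rel, kind = "relapse"))
      }
    }
  }
  dplyr::arrange(ev, .data$t_day)
}

relapse_day <- function(uncontrolled, days, need) {
  r <- rle(uncontrolled)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0) return(NA_real_)
  days[starts[hit[1]]]
}

#' @export
print.kpd_sim <- function(x, ...) {
  cat("<kpd_sim> ", nrow(x$daily), "days,", nrow(x$segments), "segments\n")
  if (nrow(x$events) > 0) {
    cat("events:\n")
    print(as.data.frame(x$events), row.names = FALSE)
  } else {
    cat("events: none\n")
  }
  invisible(x)
}
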