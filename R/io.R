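#' Write a tibble as reproducible CSV
#'
#' Comma separator, header row, "." decimal, floating point at 10
#' significant digits -- so byte-identical re-runs of deterministic
#' commands produce byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) {
    ifelse(is.finite(v), formatC(v, digits = 10, format = "g"),
           as.character(v))
  })
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize and restore a scenario definition
#'
#' Scenarios round-trip through a small JSON structure (segments with
#' duration, meal plan, treatment type and treatment arguments).
#'
#' @param scenario A [kpd_scenario()] (with a named initial state or
#'   `"healthy_fixed_point"`).
#' @param path File path.
#' @return `read_scenario()` returns a `kpd_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  segs <- purrr::map(scenario$segments, function(s) {
    list(duration = s$duration, meal_plan = s$meal_plan,
         treatment = s$treatment, until_controlled = s$until_controlled)
  })
  init <- scenario$initial_state
  if (is.numeric(init)) init <- as.list(init)
  jsonlite::write_json(list(segments = segs, initial_state = init),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(paste0("scenario file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- purrr::map(raw$segments, function(s) {
    tr <- s$treatment
    treatment <- switch(tr$type,
      none = treatment_none(),
      constant_dose = treatment_constant(
        if (is.null(tr$F_I)) NULL else as.numeric(tr$F_I)),
      titrated = treatment_titrated(as.numeric(tr$G_min)),
      abort(paste0("unknown treatment type: ", tr$type))
    )
    scenario_segment(s$duration, s$meal_plan, treatment,
                     until_controlled = isTRUE(s$until_controlled))
  })
  init <- raw$initial_state
  if (is.list(init)) {
    init <- do.call(system_state, init)
  } else {
    init <- as.character(init)
  }
  do.call(kpd_scenario, c(segs, list(initial_state = init)))
}

#' Run a configured analysis end to end
#'
#' The programmatic core of the command-line tool: dispatches on
#' `command`, runs the corresponding module, and writes tidy CSV outputs
#' plus a JSON run manifest (config echo, package version, seed) into
#' `out_dir`, enabling bit-identical re-runs of deterministic commands.
#'
#' @param command One of `"simulate"`, `"fixed-points"`, `"scan"`,
#'   `"phase-diagram"`, `"protocol"`, `"calibrate"`.
#' @param params_file Path to a parameter JSON (see [write_parameters()]);
#'   `NULL` selects the preset named by `preset`.
#' @param preset Preset label used when `params_file` is `NULL`.
#' @param scenario_file Scenario JSON for `simulate` (`NULL` uses the
#'   standard onset/remission scenario with titrated treatment).
#' @param out_dir Output directory (created if needed).
#' @param axis,grid Scan axis and grid for `scan`.
#' @param M,F_I Constant exogenous fluxes for `fixed-points`.
#' @param G_min Glucose floor for `protocol`.
#' @param seed Integer seed recorded in the manifest (and used by any
#'   stochastic command).
#' @param solver A [solver_config()].
#' @return Invisibly, a named list of written file paths.
#' @export
kpd_run <- function(command = c("simulate", "fixed-points", "scan",
                                "phase-diagram", "protocol", "calibrate"),
                    params_file = NULL, preset = "B", scenario_file = NULL,
                    out_dir = ".", axis = "M", grid = NULL,
                    M = 0, F_I = 0, G_min = 90, seed = 1,
                    solver = solver_config()) {
  command <- match.arg(command)
  params <- if (!is.null(params_file)) {
    read_parameters(params_file)
  } else {
    kpd_preset(preset)$params
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  paths <- list()

  if (command == "fixed-points") {
    fp <- find_fixed_points(params, M = M, F_I = F_I)
    paths$fixed_points <- write_result_csv(
      tidy(fp), file.path(out_dir, "fixed_points.csv"))
    jsonlite::write_json(as.list(glance(fp)),
                         file.path(out_dir, "fixed_points_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$summary <- file.path(out_dir, "fixed_points_summary.json")
  } else if (command == "scan") {
    grid <- grid %||% default_scan_grid(axis, params)
    sc <- scan_1d(params, axis, grid)
    paths$scan <- write_result_csv(tidy(sc), file.path(out_dir, "scan.csv"))
    jsonlite::write_json(
      list(axis = axis,
           bifurcations = attr(sc, "bifurcations")),
      file.path(out_dir, "bifurcations.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    paths$bifurcations <- file.path(out_dir, "bifurcations.json")
  } else if (command == "phase-diagram") {
    pd <- phase_diagram(params)
    paths$phase_diagram <- write_result_csv(
      tidy(pd), file.path(out_dir, "phase_diagram.csv"))
  } else if (command == "protocol") {
    pr <- optimal_protocol(G_min, params = params)
    paths$schedule <- write_result_csv(
      tidy(pr), file.path(out_dir, "dose_schedule.csv"))
    paths$remission <- write_result_csv(
      remission_curve(params = params), file.path(out_dir, "remission_curve.csv"))
  } else if (command == "simulate") {
    scen <- if (!is.null(scenario_file)) {
      read_scenario(scenario_file)
    } else {
      standard_onset_scenario()
    }
    sim <- simulate_scenario(scen, params, solver = solver)
    paths$trajectory <- write_result_csv(
      dplyr::rename(sim$trajectory, t_day = "t", beta_in = "beta_IN"),
      file.path(out_dir, "trajectory.csv"))
    paths$daily <- write_result_csv(sim$daily, file.path(out_dir, "daily.csv"))
    paths$events <- write_result_csv(sim$events, file.path(out_dir, "events.csv"))
  } else if (command == "calibrate") {
    write_preset_files(out_dir)
    check_preset_files(out_dir)
    paths$presets <- out_dir
  }

  manifest <- list(
    command = command, preset = if (is.null(params_file)) preset else NULL,
    params = unclass(params), seed = seed,
    package = "kpdsim",
    version = as.character(utils::packageVersion("kpdsim"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  paths$manifest <- file.path(out_dir, "run_manifest.json")
  invisible(paths)
}

default_scan_grid <- function(axis, params) {
  switch(axis,
    M = seq(0, 700, length.out = 29),
    F_I = seq(0, 5000, length.out = 26),
    k_ratio = 10^seq(0, 4, length.out = 25),
    S_I = params$S_I * seq(0.5, 1.5, length.out = 21),
    beta_TOT = params$beta_TOT * seq(0.5, 1.5, length.out = 21)
  )
}

#' The standard onset-and-remission scenario
#'
#' Thirty days of normal eating from the healthy fixed point, a month of
#' high sugar consumption, thirty untreated days, a titrated insulin
#' course (up to `treat_max` days, stopping once glucose is controlled),
#' and an insulin-free follow-up.
#'
#' @param baseline,high_sugar,untreated,treat_max,follow_up Segment
#'   durations, days.
#' @param G_min Titration floor, mg/dL.
#' @return A [kpd_scenario()].
#' @export
standard_onset_scenario <- function(baseline = 30, high_sugar = 30,
                                    untreated = 30, treat_max = 150,
                                    follow_up = 75, G_min = 90) {
  kpd_scenario(
    scenario_segment(baseline, "normal"),
    scenario_segment(high_sugar, "high_sugar"),
    scenario_segment(untreated, "normal"),
    scenario_segment(treat_max, "normal", treatment_titrated(G_min),
                     until_controlled = TRUE),
    scenario_segment(follow_up, "normal")
  )
}
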