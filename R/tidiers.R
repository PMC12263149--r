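#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fixed-point set
#'
#' @param x A `kpd_fixed_points` object.
#' @param ... Unused.
#' @return A tibble with one row per fixed point.
#' @method tidy kpd_fixed_points
#' @export
tidy.kpd_fixed_points <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.kpd_fixed_points
#' @method glance kpd_fixed_points
#' @export
glance.kpd_fixed_points <- function(x, ...) {
  st <- x[x$stability == "stable", ]
  tibble::tibble(
    regime = attr(x, "regime"),
    n_fixed_points = nrow(x),
    n_stable = nrow(st),
    G_healthy = if (any(st$branch == "healthy_high_beta"))
      st$G[st$branch == "healthy_high_beta"] else NA_real_,
    G_hyperglycemic = if (any(st$branch == "hyperglycemic_low_beta"))
      st$G[st$branch == "hyperglycemic_low_beta"] else NA_real_
  )
}

#' Tidy a bifurcation scan
#'
#' @param x A `kpd_scan` object.
#' @param ... Unused.
#' @return The scan as a plain tibble (one row per fixed point per grid
#'   value); `glance()` summarizes the regimes and bifurcation locations.
#' @method tidy kpd_scan
#' @export
tidy.kpd_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.kpd_scan
#' @method glance kpd_scan
#' @export
glance.kpd_scan <- function(x, ...) {
  bif <- attr(x, "bifurcations")
  tibble::tibble(
    axis = attr(x, "axis"),
    n_grid = dplyr::n_distinct(x$value),
    n_bifurcations = nrow(bif),
    any_bistable = any(x$regime == "bistable")
  )
}

#' Tidy a scenario simulation
#'
#' `tidy()` returns the daily aggregates; `glance()` a one-row clinical
#' summary.
#'
#' @param x A `kpd_sim` object.
#' @param ... Unused.
#' @method tidy kpd_sim
#' @export
tidy.kpd_sim <- function(x, ...) {
  x$daily
}

#' @rdname tidy.kpd_sim
#' @method glance kpd_sim
#' @export
glance.kpd_sim <- function(x, ...) {
  last10 <- dplyr::slice_tail(x$daily, n = 10)
  tibble::tibble(
    days = nrow(x$daily),
    final_G_mean_10d = mean(last10$G_mean),
    final_beta_tot = x$daily$beta_tot[nrow(x$daily)],
    crisis = "crisis_onset" %in% x$events$kind,
    remission = "remission" %in% x$events$kind,
    relapse = "relapse" %in% x$events$kind
  )
}

#' Tidy an insulin protocol
#'
#' `tidy()` returns the tabulated schedule; `glance()` the scalar summary.
#'
#' @param x A `kpd_protocol` object.
#' @param ... Unused.
#' @method tidy kpd_protocol
#' @export
tidy.kpd_protocol <- function(x, ...) {
  x$schedule
}

#' @rdname tidy.kpd_protocol
#' @method glance kpd_protocol
#' @export
glance.kpd_protocol <- function(x, ...) {
  tibble::tibble(
    G_min = x$G_min, beta_start = x$beta_start, I_star = x$I_star,
    time_to_remission = x$time_to_remission,
    dose_floor_time = x$dose_floor_time
  )
}

#' Tidy a phase diagram
#'
#' @param x A `kpd_phase_diagram` object.
#' @param ... Unused.
#' @method tidy kpd_phase_diagram
#' @export
tidy.kpd_phase_diagram <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.kpd_phase_diagram
#' @method glance kpd_phase_diagram
#' @export
glance.kpd_phase_diagram <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_no_hatch = sum(x$hatch == "no_hatch"),
    n_single_hatch = sum(x$hatch == "single_hatch"),
    n_double_hatch = sum(x$hatch == "double_hatch")
  )
}
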