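#' One-parameter bifurcation scan
#'
#' Computes the fixed-point set along a monotone grid of one control
#' parameter and locates the saddle-node bifurcations (parameter values
#' where the number of stable fixed points changes) by bisection between
#' grid cells whose regimes differ, refined to relative tolerance 1e-4.
#'
#' @param params A [model_parameters()] object.
#' @param axis One of `"M"` (glucose intake flux), `"F_I"` (insulin
#'   infusion), `"k_ratio"` (`k_IN/k_RE`, varied through `k_IN`), `"S_I"`,
#'   `"beta_TOT"`.
#' @param grid Monotone numeric grid of axis values (positive for the
#'   parameter axes; `M` and `F_I` may include zero).
#' @param G_hyper Passed to [find_fixed_points()].
#' @return An object of class `kpd_scan`: a tibble with one row per fixed
#'   point per grid value (columns `value`, `G`, `I`, `beta`, `stability`,
#'   `branch`, `regime`, `n_stable`), with attributes `axis` and
#'   `bifurcations` (tibble of refined locations).
#' @export
#' @examples
#' \donttest{
#' sc <- scan_1d(kpd_preset("B")$params, "F_I", seq(0, 4000, length.out = 21))
#' attr(sc, "bifurcations")
#' }
scan_1d <- function(params, axis = c("M", "F_I", "k_ratio", "S_I", "beta_TOT"),
                    grid, G_hyper = 300) {
  axis <- match.arg(axis)
  if (is.unsorted(grid) && is.unsorted(rev(grid))) {
    abort("grid must be monotone")
  }
  grid <- as.numeric(grid)
  if (axis %in% c("k_ratio", "S_I", "beta_TOT") && any(grid <= 0)) {
    abort("grid outside positive-parameter domain")
  }
  if (axis %in% c("M", "F_I") && any(grid < 0)) {
    abort("grid outside positive-parameter domain")
  }

  fps_at <- function(v) scan_point(params, axis, v, G_hyper)

  sets <- purrr::map(grid, fps_at)
  rows <- purrr::map2_dfr(grid, sets, function(v, fp) {
    tibble::tibble(
      value = v, G = fp$G, I = fp$I, beta = fp$beta,
      stability = fp$stability, branch = fp$branch,
      regime = attr(fp, "regime"),
      n_stable = sum(fp$stability == "stable")
    )
  })

  counts <- vapply(sets, function(fp) sum(fp$stability == "stable"), 1L)
  bif <- tibble::tibble(value = numeric(0), from = integer(0), to = integer(0))
  for (i in seq_len(length(grid) - 1)) {
    if (counts[i] != counts[i + 1]) {
      loc <- refine_bifurcation(fps_at, grid[i], grid[i + 1],
                                counts[i], counts[i + 1])
      bif <- dplyr::bind_rows(bif, tibble::tibble(
        value = loc, from = counts[i], to = counts[i + 1]
      ))
    }
  }

  structure(rows, axis = axis, bifurcations = bif, params = params,
            class = c("kpd_scan", class(rows)))
}

scan_point <- function(params, axis, v, G_hyper = 300) {
  switch(axis,
    M = find_fixed_points(params, M = v, G_hyper = G_hyper),
    F_I = find_fixed_points(params, F_I = v, G_hyper = G_hyper),
    k_ratio = find_fixed_points(
      update_parameters(params, k_IN = v * params$k_RE), G_hyper = G_hyper),
    S_I = find_fixed_points(update_parameters(params, S_I = v),
                            G_hyper = G_hyper),
    beta_TOT = find_fixed_points(update_parameters(params, beta_TOT = v),
                                 G_hyper = G_hyper)
  )
}

refine_bifurcation <- function(fps_at, lo, hi, count_lo, count_hi,
                               rel_tol = 1e-4) {
  tol <- rel_tol * max(abs(lo), abs(hi), 1e-8)
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    cm <- sum(fps_at(mid)$stability == "stable")
    if (cm == count_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.kpd_scan <- function(x, ...) {
  cat("<kpd_scan>  axis:", attr(x, "axis"), "\n")
  bif <- attr(x, "bifurcations")
  if (nrow(bif) > 0) {
    cat("bifurcations at:", paste(format(bif$value, digits = 6), collapse = ", "), "\n")
  }
  NextMethod()
}

# quasi-static adaptation: reduce c below c_max if the fasting fixed point
# would otherwise fall below G_0; returns the adapted c
quasi_static_c <- function(params) {
  fp <- find_fixed_points(params, check_jacobian = FALSE)
  G_fast <- min(fp$G[fp$stability == "stable"])
  if (G_fast >= params$G_0) return(params$c_max)
  # adaptation lowers c until the healthy fixed point sits at G_0
  I_star <- insulin_for_target(params$G_0, params)
  rho <- params$k_IN / params$k_RE
  g0 <- inactivation_fraction(params$G_0, params$K_g)
  f0 <- secretion_fraction(params$G_0, params$K_f)
  c_ad <- params$gamma * I_star * (1 + rho * g0) / (params$beta_TOT * f0)
  min(c_ad, params$c_max)
}

#' Phase diagram over insulin sensitivity and beta-cell reserve
#'
#' Classifies the fasting fixed-point structure over a grid of relative
#' multipliers of `S_I` and `beta_TOT` (both applied to `params`), with
#' the secretory capacity following the quasi-static adaptation rule:
#' `c = c_max` unless the fasting glucose would fall below `G_0`, in which
#' case `c` is reduced so the fasting point sits exactly at `G_0`.
#'
#' Each cell records the lowest stable fasting glucose and a regime class:
#' `no_hatch` (single stable high-beta point), `single_hatch` (bistable --
#' KPD susceptibility), `double_hatch` (only the low-beta point remains;
#' insulin treatment alone cannot restore function). The glucose value is
#' reported uncapped; the conventional 130 mg/dL display cap is applied
#' only by the plotting method.
#'
#' @param params A [model_parameters()] object (typically a calibrated
#'   preset).
#' @param S_I_grid,beta_TOT_grid Positive relative multipliers.
#' @param G_hyper Threshold used to label monostable points, mg/dL.
#' @return An object of class `kpd_phase_diagram`: a tibble with columns
#'   `S_I_rel`, `beta_TOT_rel`, `fasting_G`, `regime`, `hatch`,
#'   `n_stable`, `c_adapted`.
#' @export
phase_diagram <- function(params,
                          S_I_grid = seq(0.5, 1.5, length.out = 11),
                          beta_TOT_grid = seq(0.5, 1.5, length.out = 11),
                          G_hyper = 300) {
  if (any(S_I_grid <= 0) || any(beta_TOT_grid <= 0)) {
    abort("multiplier grids must be positive")
  }
  cells <- tidyr::expand_grid(S_I_rel = S_I_grid, beta_TOT_rel = beta_TOT_grid)
  res <- purrr::pmap_dfr(cells, function(S_I_rel, beta_TOT_rel) {
    p <- update_parameters(params,
                           S_I = params$S_I * S_I_rel,
                           beta_TOT = params$beta_TOT * beta_TOT_rel)
    c_ad <- quasi_static_c(p)
    fp <- find_fixed_points(p, c_sec = c_ad, G_hyper = G_hyper,
                            check_jacobian = FALSE)
    stable <- fp[fp$stability == "stable", ]
    n_stable <- nrow(stable)
    hatch <- if (n_stable >= 2) {
      "single_hatch"
    } else if (stable$branch[1] == "hyperglycemic_low_beta") {
      "double_hatch"
    } else {
      "no_hatch"
    }
    tibble::tibble(
      S_I_rel = S_I_rel, beta_TOT_rel = beta_TOT_rel,
      fasting_G = min(stable$G), regime = attr(fp, "regime"),
      hatch = hatch, n_stable = n_stable, c_adapted = c_ad
    )
  })
  structure(res, params = params,
            class = c("kpd_phase_diagram", class(res)))
}
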