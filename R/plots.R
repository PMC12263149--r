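#' Plot a simulated clinical scenario
#'
#' Daily mean glucose (solid line) with the normoglycemia (80 mg/dL) and
#' diabetes-control (130 mg/dL) reference levels, segment shading for
#' high-sugar and insulin-treatment periods, and the active beta-cell
#' fraction as a secondary panel value.
#'
#' @param object A `kpd_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kpd_sim
#' @export
autoplot.kpd_sim <- function(object, ...) {
  daily <- object$daily
  segs <- object$segments
  shade <- dplyr::filter(segs, .data$meal_plan == "high_sugar" |
                           .data$treatment != "none")
  shade$fill <- ifelse(shade$meal_plan == "high_sugar",
                       "high sugar", "insulin")
  p <- ggplot2::ggplot(daily, ggplot2::aes(x = .data$day))
  if (nrow(shade) > 0) {
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_day, xmax = .data$end_day,
                   ymin = -Inf, ymax = Inf, fill = .data$fill),
      alpha = 0.15)
  }
  p +
    ggplot2::geom_hline(yintercept = 80, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 130, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$G_mean)) +
    ggplot2::scale_fill_manual(values = c("high sugar" = "red",
                                          "insulin" = "blue"),
                               name = NULL) +
    ggplot2::labs(x = "time (days)", y = "daily mean glucose (mg/dL)")
}

#' Plot a one-parameter bifurcation diagram
#'
#' Stable branches as solid points/lines, unstable as dashed; detected
#' saddle-node locations as vertical dashed lines.
#'
#' @param object A `kpd_scan` object.
#' @param y Which state to plot on the vertical axis: `"G"` or `"beta"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kpd_scan
#' @export
autoplot.kpd_scan <- function(object, y = c("G", "beta"), ...) {
  y <- match.arg(y)
  bif <- attr(object, "bifurcations")
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$value, y = .data[[y]],
                 colour = .data$branch, linetype = .data$stability)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    ggplot2::labs(x = attr(object, "axis"), y = y)
  if (nrow(bif) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = bif$value, linetype = "dashed")
  }
  p
}

#' Plot a phase diagram
#'
#' Fasting glucose as fill (capped at 130 mg/dL for display, as is
#' conventional; the underlying tibble is uncapped), with the bistable
#' (single-hatch) and insulin-dependent (double-hatch) regimes marked by
#' overlay points.
#'
#' @param object A `kpd_phase_diagram` object.
#' @param cap Display cap on fasting glucose, mg/dL.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kpd_phase_diagram
#' @export
autoplot.kpd_phase_diagram <- function(object, cap = 130, ...) {
  d <- tibble::as_tibble(object)
  d$G_display <- pmin(d$fasting_G, cap)
  hatch <- dplyr::filter(d, .data$hatch != "no_hatch")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$S_I_rel,
                                       y = .data$beta_TOT_rel)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$G_display)) +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "red",
                                 name = "fasting G (mg/dL)") +
    ggplot2::labs(x = "relative insulin sensitivity",
                  y = "relative beta-cell pool")
  if (nrow(hatch) > 0) {
    p <- p + ggplot2::geom_point(
      data = hatch, ggplot2::aes(shape = .data$hatch), size = 1.5)
  }
  p
}

#' Plot an insulin dose schedule
#'
#' @param object A `kpd_protocol` object.
#' @param ... Unused.
#' @return A ggplot object showing the infusion rate over time.
#' @method autoplot kpd_protocol
#' @export
autoplot.kpd_protocol <- function(object, ...) {
  ggplot2::ggplot(object$schedule, ggplot2::aes(x = .data$t, y = .data$F_I)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since treatment start (days)",
                  y = "insulin infusion (uU/mL/day)",
                  title = paste0("G_min = ", object$G_min, " mg/dL"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
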