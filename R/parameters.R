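#' Model parameters for the KPD glucose-insulin system
#'
#' Bundles every rate constant of the model: the fast glucose-insulin
#' feedback loop, the reversible beta-cell inactivation/reactivation cycle,
#' the slow permanent beta-cell death process, and the secretory-capacity
#' adaptation ceiling. Units follow the clinical convention used throughout
#' the package: time in days, glucose in mg/dL, insulin in uU/mL.
#'
#' @param m_0 Hepatic-production scale, mg/dL * (uU/mL) / day. Endogenous
#'   glucose production is `m_0 / (I_0 + I)`.
#' @param I_0 Hepatic-suppression insulin constant, uU/mL.
#' @param S_E Insulin-independent glucose clearance rate (glucose
#'   effectiveness), 1/day.
#' @param S_I Insulin sensitivity, mL/uU/day.
#' @param gamma Insulin clearance rate, 1/day.
#' @param K_f Half-max glucose of the insulin-secretion response `f(G)`,
#'   mg/dL.
#' @param K_g Half-max glucose of the reversible-inactivation response
#'   `g(G)`, mg/dL. Bistability requires `K_g` well above `K_f`.
#' @param K_h Half-max glucose of the death-rate response `h(G)`, mg/dL.
#' @param k_IN Reversible beta-cell inactivation rate scale, 1/day.
#' @param k_RE Beta-cell reactivation rate, 1/day.
#' @param k_D Permanent beta-cell death rate scale, 1/day.
#' @param beta_TOT Initial total beta-cell pool (active + inactive),
#'   dimensionless fraction; decays only through `k_D`.
#' @param c_max Maximum per-beta-cell secretion capacity, uU/mL/day;
#'   `beta * c * f(G)` is the insulin secretion flux.
#' @param G_0 Adaptation target fasting glucose, mg/dL.
#'
#' @return An object of class `kpd_parameters` (a named list).
#' @seealso [canonical_parameters()], [kpd_preset()], [write_parameters()]
#' @export
#' @examples
#' p <- canonical_parameters()
#' p$S_I
model_parameters <- function(m_0, I_0, S_E, S_I, gamma,
                             K_f, K_g, K_h,
                             k_IN, k_RE, k_D,
                             beta_TOT = 1, c_max, G_0 = 80) {
  p <- list(
    m_0 = m_0, I_0 = I_0, S_E = S_E, S_I = S_I, gamma = gamma,
    K_f = K_f, K_g = K_g, K_h = K_h,
    k_IN = k_IN, k_RE = k_RE, k_D = k_D,
    beta_TOT = beta_TOT, c_max = c_max, G_0 = G_0
  )
  validate_parameters(p)
}

parameter_fields <- function() {
  c("m_0", "I_0", "S_E", "S_I", "gamma", "K_f", "K_g", "K_h",
    "k_IN", "k_RE", "k_D", "beta_TOT", "c_max", "G_0")
}

validate_parameters <- function(p) {
  fields <- parameter_fields()
  missing <- setdiff(fields, names(p))
  if (length(missing) > 0) {
    abort(paste0("missing parameter field(s): ", paste(missing, collapse = ", ")))
  }
  p <- p[fields]
  vals <- unlist(p)
  if (!all(is.finite(vals))) {
    abort("all model parameters must be finite numbers")
  }
  if (any(vals <= 0)) {
    bad <- names(vals)[vals <= 0]
    abort(paste0("model parameters must be strictly positive: ",
                 paste(bad, collapse = ", ")))
  }
  if (p$K_g <= p$K_f) {
    abort("K_g must exceed K_f: the bistability mechanism requires the inactivation response to engage well above the secretion response")
  }
  structure(p, class = "kpd_parameters")
}

#' @export
print.kpd_parameters <- function(x, ...) {
  cat("<kpd_parameters>\n")
  print(tibble::as_tibble(unclass(x)))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, revalidated.
#'
#' @param params A [model_parameters()] object.
#' @param ... Named fields to override.
#' @return A `kpd_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  dots <- list(...)
  if (length(dots) == 0) return(params)
  unknown <- setdiff(names(dots), parameter_fields())
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter field(s): ", paste(unknown, collapse = ", ")))
  }
  validate_parameters(modifyList(unclass(params), dots))
}

#' Secretory-capacity adaptation policy
#'
#' The per-cell secretion capacity `c` adapts slowly toward a target fasting
#' glucose `G_0`, with a hard ceiling at `c_max`. Three modes are supported:
#'
#' * `"frozen_at_max"` (default): `c = c_max` throughout. This is the
#'   advanced-prediabetes assumption under which the clinical scenarios run:
#'   beta cells have already exhausted their adaptive reserve.
#' * `"quasi_static"`: `c` is set instantaneously so that fasting glucose
#'   equals `G_0` whenever that is achievable with `c <= c_max`, and `c_max`
#'   otherwise. Used by [phase_diagram()].
#' * `"dynamic"`: `dc/dt = k_a * (G - G_0)`, clipped so `c` stays in
#'   `(0, c_max]`. The model constrains only the sign of the adaptation
#'   rule; this linear form is the simplest rule satisfying it.
#'
#' @param mode One of `"frozen_at_max"`, `"quasi_static"`, `"dynamic"`.
#' @param k_a Adaptation rate for dynamic mode,
#'   (uU/mL/day) per (mg/dL) per day. Default: 1% of `c_max` per mg/dL per
#'   30 days, supplied as a function of `c_max` at use time when `NULL`.
#' @param G_f Optional fixed fasting-glucose input to the rule; when `NULL`
#'   the instantaneous glucose is used.
#' @return An object of class `kpd_adaptation`.
#' @export
adaptation_policy <- function(mode = c("frozen_at_max", "quasi_static", "dynamic"),
                              k_a = NULL, G_f = NULL) {
  mode <- match.arg(mode)
  if (!is.null(k_a) && (!is.numeric(k_a) || k_a < 0)) {
    abort("k_a must be a non-negative number")
  }
  structure(list(mode = mode, k_a = k_a, G_f = G_f), class = "kpd_adaptation")
}

default_k_a <- function(params) 0.01 * params$c_max / 30

#' Write or read a parameter set as a flat JSON config
#'
#' The file is a flat key-value object whose keys are exactly the
#' [model_parameters()] field names, values in the package's standard units.
#'
#' @param params A `kpd_parameters` object.
#' @param path File path.
#' @return `write_parameters()` returns `path` invisibly; `read_parameters()`
#'   returns a validated `kpd_parameters` object.
#' @export
write_parameters <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @param policy An [adaptation_policy()].
#' @export
write_adaptation_policy <- function(policy, path) {
  jsonlite::write_json(unclass(policy), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_adaptation_policy <- function(path) {
  if (!file.exists(path)) abort(paste0("adaptation file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  adaptation_policy(mode = raw$mode, k_a = raw$k_a, G_f = raw$G_f)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) abort(paste0("parameter file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw))) {
    abort("parameter file must be a flat JSON object of named numbers")
  }
  validate_parameters(lapply(raw, as.numeric))
}
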