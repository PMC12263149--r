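#' Glucose response functions
#'
#' The three Hill-type responses of the model, all of the form
#' `G^2 / (G^2 + K^2)`: `secretion_fraction()` is the normalized insulin
#' secretion response `f(G)`, `inactivation_fraction()` the reversible
#' beta-cell inactivation response `g(G)`, and `death_fraction()` the
#' permanent death response `h(G)`. Each is strictly increasing in `G`,
#' bounded in `[0, 1)`, and equals 1/2 at its half-max constant.
#'
#' The inactivation half-max `K_g` is far above the secretion half-max
#' `K_f`, so `g` is tiny at physiological glucose (about 6e-4 at 100 mg/dL
#' with the canonical constants) but still rising where `f` has plateaued --
#' the ingredient that lets total secretion fall with rising glucose and
#' produces bistability.
#'
#' @param G Plasma glucose, mg/dL (vectorized, non-negative).
#' @param K_f,K_g,K_h Half-max constants, mg/dL.
#' @return Dimensionless fraction in `[0, 1)`.
#' @export
#' @examples
#' secretion_fraction(110, K_f = sqrt(20000))
#' inactivation_fraction(100, K_g = derive_K_g())
secretion_fraction <- function(G, K_f) {
  hill2(G, K_f)
}

#' @rdname secretion_fraction
#' @export
inactivation_fraction <- function(G, K_g) {
  hill2(G, K_g)
}

#' @rdname secretion_fraction
#' @export
death_fraction <- function(G, K_h) {
  hill2(G, K_h)
}

hill2 <- function(G, K) {
  if (any(!is.finite(G)) || any(G < 0)) {
    abort("glucose must be finite and non-negative")
  }
  if (!is.numeric(K) || length(K) != 1 || !is.finite(K) || K <= 0) {
    abort("half-max constant must be a single positive number")
  }
  G2 <- G^2
  G2 / (G2 + K^2)
}

#' Endogenous (hepatic) glucose production
#'
#' Insulin-suppressed hepatic glucose production, `m_0 / (I_0 + I)`:
#' maximal at zero insulin and halved at `I = I_0`, where it equals the
#' reference production rate `R_ref = m_0 / (2 I_0)`.
#'
#' @param I Plasma insulin, uU/mL (vectorized, non-negative).
#' @param params A [model_parameters()] object (only `m_0` and `I_0` used).
#' @return Glucose flux, mg/dL/day.
#' @export
hepatic_production <- function(I, params) {
  if (any(!is.finite(I)) || any(I < 0)) {
    abort("insulin must be finite and non-negative")
  }
  params$m_0 / (params$I_0 + I)
}
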