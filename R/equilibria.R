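#' Steady-state active beta-cell fraction at a given glucose
#'
#' With the reversible inactivation cycle equilibrated (and permanent death
#' neglected), the active fraction settles at
#' `beta_TOT / (1 + (k_IN / k_RE) g(G))`: decreasing in `G`, equal to the
#' full pool at `G = 0`.
#'
#' @param G Plasma glucose, mg/dL (vectorized).
#' @param params A [model_parameters()] object.
#' @return Active beta-cell fraction.
#' @export
steady_beta <- function(G, params) {
  rho <- params$k_IN / params$k_RE
  params$beta_TOT / (1 + rho * inactivation_fraction(G, params$K_g))
}

# ---- polynomial arithmetic (ascending coefficient vectors) ----

polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

polyadd <- function(...) {
  ps <- list(...)
  n <- max(vapply(ps, length, 1L))
  out <- numeric(n)
  for (p in ps) out[seq_along(p)] <- out[seq_along(p)] + p
  out
}

# multiply by G^k
polyshift <- function(p, k) c(numeric(k), p)

polyeval <- function(p, x) {
  out <- 0
  for (i in rev(seq_along(p))) out <- out * x + p[i]
  out
}

#' Roots of a polynomial via its companion matrix
#'
#' Builds the companion matrix of the monic polynomial with ascending
#' coefficients `coefs` (constant term first) and returns its eigenvalues.
#' Trailing coefficients that are negligible relative to the largest are
#' trimmed first.
#'
#' @param coefs Numeric vector of polynomial coefficients, ascending.
#' @return Complex vector of roots.
#' @export
companion_roots <- function(coefs) {
  scale <- max(abs(coefs))
  if (!is.finite(scale) || scale == 0) {
    abort("degenerate-parameter error: all polynomial coefficients vanish")
  }
  p <- coefs / scale
  while (length(p) > 1 && p[length(p)] == 0) p <- p[-length(p)]
  n <- length(p) - 1
  if (n < 1) abort("degenerate-parameter error: polynomial has degree zero")
  # rescale the variable so roots are O(1); raw coefficients can span many
  # orders of magnitude, which ruins the companion eigenproblem
  s <- (abs(p[1]) / abs(p[n + 1]))^(1 / n)
  if (!is.finite(s) || s <= 0) s <- 1
  ps <- p * s^(0:n)
  monic <- ps / ps[n + 1]
  if (n == 1) return(-monic[1] * s)
  C <- matrix(0, n, n)
  C[cbind(2:n, 1:(n - 1))] <- 1
  C[, n] <- -monic[1:n]
  x <- eigen(C, only.values = TRUE)$values
  # Newton polish in the scaled variable
  dmonic <- monic[-1] * seq_len(n)
  for (k in 1:3) {
    fx <- polyeval_c(monic, x)
    dfx <- polyeval_c(dmonic, x)
    step <- ifelse(abs(dfx) > 0, fx / dfx, 0)
    step <- ifelse(abs(step) < 0.5 * pmax(abs(x), 1e-8), step, 0)
    x <- x - step
  }
  x * s
}

polyeval_c <- function(p, x) {
  out <- rep(0 + 0i, length(x))
  for (i in rev(seq_along(p))) out <- out * x + p[i]
  out
}

#' Fixed-point polynomial of the fast subsystem
#'
#' At a fixed active fraction `beta`, the steady-state glucose of the fast
#' glucose-insulin subsystem under constant intake `M` and infusion `F_I`
#' satisfies a balance between insulin-suppressed hepatic production plus
#' intake, and glucose disposal. Clearing the two denominators (the insulin
#' balance `I = (beta c f(G) + F_I)/gamma` substituted into the hepatic
#' term, and the Hill denominator of `f(G)`) turns this balance into a
#' quintic in `G`, whose coefficients this function returns.
#'
#' @param beta Active beta-cell fraction (uses secretion capacity
#'   `c = c_sec`).
#' @param params A [model_parameters()] object.
#' @param M Constant glucose intake flux, mg/dL/day.
#' @param F_I Constant insulin infusion, uU/mL/day.
#' @param c_sec Per-cell secretion capacity; defaults to `c_max`.
#' @return Numeric vector of 6 coefficients, ascending powers of `G`.
#' @export
fixed_point_polynomial <- function(beta, params, M = 0, F_I = 0,
                                   c_sec = params$c_max) {
  if (beta < 0) abort("beta must be non-negative")
  gam <- params$gamma
  D <- c(params$K_f^2, 0, 1)            # G^2 + K_f^2
  A <- beta * c_sec
  E <- F_I + params$I_0 * gam
  u <- params$S_E * gam + params$S_I * F_I
  P <- c(E * params$K_f^2, 0, A + E)    # A G^2 + E D
  Q <- c(u * params$K_f^2, 0, u + params$S_I * A)
  poly <- polyadd(
    params$m_0 * gam^2 * polymul(D, D),
    M * gam * polymul(D, P),
    -polymul(c(0, 1), polymul(Q, P))
  )
  if (max(abs(poly)) == 0) {
    abort("degenerate-parameter error: all polynomial coefficients vanish")
  }
  poly
}

# Un-cleared steady-state residual of the fast subsystem at (G, beta):
# production + intake - disposal, with insulin slaved to secretion.
glucose_balance_residual <- function(G, beta, params, M = 0, F_I = 0,
                                     c_sec = params$c_max) {
  I <- (beta * c_sec * secretion_fraction(G, params$K_f) + F_I) / params$gamma
  params$m_0 / (params$I_0 + I) + M - G * (params$S_E + params$S_I * I)
}

# magnitude scale of the residual, for relative tolerance checks
glucose_balance_scale <- function(G, beta, params, M = 0, F_I = 0,
                                  c_sec = params$c_max) {
  I <- (beta * c_sec * secretion_fraction(G, params$K_f) + F_I) / params$gamma
  params$m_0 / (params$I_0 + I) + M + G * (params$S_E + params$S_I * I)
}

filter_real_positive <- function(roots, resid_fn, scale_fn,
                                 rel_tol = 1e-8, dedup = 1e-6,
                                 G_max = 5000) {
  re <- Re(roots)
  keep <- abs(Im(roots)) < 1e-8 * pmax(abs(roots), 1) & re > 0 & re <= G_max
  G <- sort(re[keep])
  if (length(G) == 0) return(numeric(0))
  ok <- vapply(G, function(x) {
    abs(resid_fn(x)) <= rel_tol * scale_fn(x)
  }, logical(1))
  G <- G[ok]
  if (length(G) <= 1) return(G)
  out <- G[1]
  for (x in G[-1]) if (x - out[length(out)] > dedup) out <- c(out, x)
  out
}

#' Steady-state glucose values of the fast subsystem at fixed beta
#'
#' Solves the quintic from [fixed_point_polynomial()] with the companion
#' matrix, keeps real positive roots within the physical search domain
#' (production is bounded by `m_0/I_0`, so roots cannot exceed
#' `m_0/(S_E I_0)`; the domain cap of 5000 mg/dL leaves margin), verifies
#' each root against the un-cleared balance residual at relative tolerance
#' 1e-8, and deduplicates within 1e-6 mg/dL.
#'
#' @inheritParams fixed_point_polynomial
#' @return Sorted numeric vector of glucose roots (possibly empty).
#' @export
solve_glucose <- function(beta, params, M = 0, F_I = 0,
                          c_sec = params$c_max) {
  poly <- fixed_point_polynomial(beta, params, M = M, F_I = F_I, c_sec = c_sec)
  roots <- companion_roots(poly)
  filter_real_positive(
    roots,
    resid_fn = function(G) glucose_balance_residual(G, beta, params, M, F_I, c_sec),
    scale_fn = function(G) glucose_balance_scale(G, beta, params, M, F_I, c_sec)
  )
}

#' Slow flow of the active beta-cell fraction with the fast subsystem
#' equilibrated
#'
#' On timescales of weeks the permanent death process is negligible and the
#' glucose-insulin pair can be treated as instantaneously equilibrated at
#' the current beta. The remaining one-dimensional flow is
#' `-k_IN g(G_hat(beta)) beta + k_RE (beta_TOT - beta)`, where
#' `G_hat(beta)` is the (numerically asserted unique) fast-subsystem
#' glucose equilibrium.
#'
#' @inheritParams fixed_point_polynomial
#' @return `dbeta/dt` (1/day).
#' @export
reduced_flow <- function(beta, params, M = 0, F_I = 0,
                         c_sec = params$c_max) {
  G <- solve_glucose(beta, params, M = M, F_I = F_I, c_sec = c_sec)
  if (length(G) == 0) {
    abort("no fast-subsystem equilibrium found (nonphysical parameters)")
  }
  if (length(G) > 1) {
    abort(paste0("ambiguity error: multiple fast-subsystem equilibria at beta = ",
                 format(beta), ": G = ", paste(format(G), collapse = ", ")))
  }
  g <- inactivation_fraction(G, params$K_g)
  -params$k_IN * g * beta + params$k_RE * (params$beta_TOT - beta)
}

# self-consistency polynomial: beta slaved to steady_beta(G); degree 9
self_consistent_polynomial <- function(params, M = 0, F_I = 0,
                                       c_sec = params$c_max,
                                       beta_TOT = params$beta_TOT) {
  gam <- params$gamma
  rho <- params$k_IN / params$k_RE
  D <- c(params$K_f^2, 0, 1)                      # f denominator
  W <- c(params$K_g^2, 0, 1 + rho)                # (1+rho) G^2 + K_g^2
  CV <- beta_TOT * c_sec * c(params$K_g^2, 0, 1)  # c * beta(G) * W
  E <- F_I + params$I_0 * gam
  u <- params$S_E * gam + params$S_I * F_I
  DW <- polymul(D, W)
  Pw <- polyadd(polyshift(CV, 2), E * DW)         # P(G) * W(G)
  Qw <- polyadd(params$S_I * polyshift(CV, 2), u * DW)
  polyadd(
    params$m_0 * gam^2 * polymul(polymul(D, D), polymul(W, W)),
    M * gam * polymul(D, polymul(Pw, W)),
    -polymul(c(0, 1), polymul(Qw, Pw))
  )
}

self_consistent_residual <- function(G, params, M = 0, F_I = 0,
                                     c_sec = params$c_max,
                                     beta_TOT = params$beta_TOT) {
  rho <- params$k_IN / params$k_RE
  beta <- beta_TOT / (1 + rho * inactivation_fraction(G, params$K_g))
  glucose_balance_residual(G, beta, params, M, F_I, c_sec)
}

self_consistent_scale <- function(G, params, M = 0, F_I = 0,
                                  c_sec = params$c_max,
                                  beta_TOT = params$beta_TOT) {
  rho <- params$k_IN / params$k_RE
  beta <- beta_TOT / (1 + rho * inactivation_fraction(G, params$K_g))
  glucose_balance_scale(G, beta, params, M, F_I, c_sec)
}

#' Fixed points of the reduced system
#'
#' Finds all equilibria of the slow dynamics (fast subsystem equilibrated,
#' permanent death neglected) by substituting the steady active fraction
#' [steady_beta()] into the fast-subsystem balance, clearing denominators
#' into a degree-9 polynomial in `G`, and solving with the companion
#' matrix. Stability is judged on the one-dimensional reduced flow
#' ([reduced_flow()]) by a central finite difference of its beta-derivative
#' (relative step 1e-6); the full 4-D Jacobian of the fast+slow system
#' (with `k_D = 0`) is computed as a cross-check and any disagreement
#' raises a warning.
#'
#' Branch labels: in a bistable set the lower-G stable point is the
#' healthy high-beta branch, the higher-G stable point the hyperglycemic
#' low-beta branch, and the unstable point intermediate. A monostable
#' point is labelled hyperglycemic when its glucose exceeds
#' `G_hyper` (the branches merge smoothly at low `k_IN/k_RE`, so no
#' structural discriminator exists there).
#'
#' @inheritParams fixed_point_polynomial
#' @param c_sec Per-cell secretion capacity (defaults to `c_max`).
#' @param G_hyper Glucose threshold used to label monostable points,
#'   mg/dL.
#' @param check_jacobian Cross-check stability against the full Jacobian?
#' @return An object of class `kpd_fixed_points`: a tibble with columns
#'   `G`, `I`, `beta`, `beta_IN`, `stability`, `branch`, ordered by
#'   ascending `G`, with attribute `regime` (one of `monostable_healthy`,
#'   `bistable`, `monostable_hyperglycemic`).
#' @export
#' @examples
#' fp <- find_fixed_points(kpd_preset("B")$params)
#' fp
find_fixed_points <- function(params, M = 0, F_I = 0,
                              c_sec = params$c_max,
                              G_hyper = 300,
                              check_jacobian = TRUE) {
  poly <- self_consistent_polynomial(params, M = M, F_I = F_I, c_sec = c_sec)
  roots <- companion_roots(poly)
  G <- filter_real_positive(
    roots,
    resid_fn = function(x) self_consistent_residual(x, params, M, F_I, c_sec),
    scale_fn = function(x) self_consistent_scale(x, params, M, F_I, c_sec)
  )
  if (length(G) == 0) {
    abort("no fixed point found; positive parameters always admit at least one")
  }
  beta <- steady_beta(G, params)
  I <- (beta * c_sec * secretion_fraction(G, params$K_f) + F_I) / params$gamma
  stability <- vapply(beta, function(b) {
    h <- 1e-6 * max(b, 1e-12)
    dphi <- (reduced_flow(b + h, params, M, F_I, c_sec) -
               reduced_flow(b - h, params, M, F_I, c_sec)) / (2 * h)
    if (dphi < 0) "stable" else "unstable"
  }, character(1))

  if (check_jacobian) {
    jac_stab <- vapply(seq_along(G), function(i) {
      jacobian_stable(G[i], I[i], beta[i], params, M, F_I, c_sec)
    }, logical(1))
    mism <- which((stability == "stable") != jac_stab)
    if (length(mism) > 0) {
      warn(paste0("reduced-flow and full-Jacobian stability disagree at G = ",
                  paste(format(G[mism], digits = 6), collapse = ", ")))
    }
  }

  n_stable <- sum(stability == "stable")
  branch <- rep("intermediate", length(G))
  stable_idx <- which(stability == "stable")
  if (n_stable >= 2) {
    branch[stable_idx[1]] <- "healthy_high_beta"
    branch[stable_idx[length(stable_idx)]] <- "hyperglycemic_low_beta"
    if (length(stable_idx) > 2) {
      branch[stable_idx[-c(1, length(stable_idx))]] <- "intermediate"
    }
  } else if (n_stable == 1) {
    branch[stable_idx] <-
      if (G[stable_idx] > G_hyper) "hyperglycemic_low_beta" else "healthy_high_beta"
  }

  regime <- if (n_stable >= 2) {
    "bistable"
  } else if (branch[stable_idx] == "healthy_high_beta") {
    "monostable_healthy"
  } else {
    "monostable_hyperglycemic"
  }

  pts <- tibble::tibble(
    G = G, I = I, beta = beta,
    beta_IN = params$beta_TOT - beta,
    stability = stability, branch = branch
  )
  structure(pts, regime = regime, params = params, M = M, F_I = F_I,
            c_sec = c_sec,
            class = c("kpd_fixed_points", class(pts)))
}

# full 4-D Jacobian (G, I, beta, beta_IN) with k_D = 0 and frozen c;
# TRUE if all eigenvalue real parts are negative
jacobian_stable <- function(G, I, beta, params, M, F_I, c_sec) {
  p0 <- update_parameters(params, k_D = 1e-300)
  sched <- exogenous_schedule(M = M, F_I = F_I)
  y0 <- c(G = G, I = I, beta = beta, beta_IN = params$beta_TOT - beta, c = c_sec)
  fr <- function(y) {
    kpd_rhs(c(y, c = c_sec), 0, p0, sched, adaptation_policy())[1:4]
  }
  y <- y0[1:4]
  n <- 4L
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * max(abs(y[j]), 1e-6)
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- max(ym[j] - h, 0)
    J[, j] <- (fr(yp) - fr(ym)) / (yp[j] - ym[j])
  }
  all(Re(eigen(J, only.values = TRUE)$values) < 1e-8)
}

#' @export
print.kpd_fixed_points <- function(x, ...) {
  cat("<kpd_fixed_points>  regime:", attr(x, "regime"), "\n")
  NextMethod()
}
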