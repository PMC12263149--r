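---
title: "A bistable glucotoxicity model of ketosis-prone diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable glucotoxicity model of ketosis-prone diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpdsim)
```

## The clinical phenomenon and the model

Ketosis-prone diabetes (KPD) is a subtype of type 2 diabetes that presents
like type 1 — a sudden hyperglycemic crisis, often after a period of heavy
sugar consumption — yet most patients, after weeks to months of insulin
treatment, can stop insulin entirely and maintain near-normal glucose.
`kpdsim` implements a deliberately minimal dynamical model of this
phenomenon built on one hypothesis: in addition to the slow, permanent
glucotoxic loss of pancreatic β cells that drives ordinary type 2 diabetes
progression, there is a much faster glucotoxicity that is *reversible* —
hyperglycemia pushes β cells into an inactive, non-secreting phenotype from
which they recover once glucose is controlled.

The state variables are plasma glucose $G$ (mg/dL), plasma insulin $I$
(µU/mL), the active and inactive β-cell fractions $\beta$ and
$\beta_{IN}$, and the per-cell secretory capacity $c$:

$$\frac{dG}{dt} = M(t) + \frac{m_0}{I_0 + I} - (S_E + S_I I)\,G$$
$$\frac{dI}{dt} = \beta\, c\, f(G) - \gamma I + F_I(t)$$
$$\frac{d\beta}{dt} = -\left(k_{IN}\, g(G) + k_D\, h(G)\right)\beta
  + k_{RE}\,\beta_{IN}$$
$$\frac{d\beta_{IN}}{dt} = -\left(k_{RE} + k_D\, h(G)\right)\beta_{IN}
  + k_{IN}\, g(G)\,\beta$$

$M(t)$ is meal intake and $F_I(t)$ exogenous insulin, both non-negative
fluxes. Hepatic glucose production $m_0/(I_0+I)$ is suppressed by insulin;
disposal has an insulin-independent part ($S_E$, glucose effectiveness)
and an insulin-dependent part ($S_I$, insulin sensitivity). All three
glucose responses are Hill functions with exponent 2,
$x^2/(x^2+K^2)$: $f$ (secretion, half-max $K_f \approx 141$ mg/dL), $g$
(reversible inactivation) and $h$ (permanent death). The slow adaptation
of $c$ toward a fasting-glucose target $G_0 = 80$ mg/dL is capped at
$c_{\max}$; every clinical scenario here is run in advanced prediabetes,
where adaptation is saturated and $c$ is frozen at $c_{\max}$.

The mechanism that makes this more than a homeostat is the placement of
$K_g \gg K_f$: at physiological glucose $g$ is tiny
($g(100) \approx 6\times 10^{-4}$), but it keeps rising where $f$ has long
plateaued. Once the reversible cycle equilibrates, total secretion
$c\,\beta(G)\,f(G)$ therefore *falls* with rising glucose over a range —
a positive feedback loop (high glucose → fewer active cells → less insulin
→ higher glucose) that produces a classic bistable toggle switch. Timescales
are strongly separated: glucose/insulin equilibrate in minutes–hours,
inactivation/reactivation act over days–weeks ($k_{IN} g$, $k_{RE}$), and
permanent death over months–years ($k_D h$).

## Parameters, units, and calibration

All times are in days, glucose in mg/dL, insulin in µU/mL. The shared
constants (see `canonical_parameters()`) adopt a standard β-cell-mass
modelling lineage: $S_E = 1.44$/day, $S_I = 0.72$ mL/µU/day,
$\gamma = 432$/day, $K_f = \sqrt{20000}$ mg/dL, and a reference hepatic
production $R_{\mathrm{ref}} = 864$ mg/dL/day. Production is
insulin-suppressed with $I_0 = 5$ µU/mL and $m_0 = 2 I_0 R_{\mathrm{ref}}$,
so production equals $R_{\mathrm{ref}}$ exactly at $I = I_0$. Two
self-checks pin the operating point: the insulin that holds fasting glucose
at 110 mg/dL computes to 7.05 µU/mL, and hepatic production there is about
17% below $R_{\mathrm{ref}}$ — both in line with the clinically expected
values ("roughly 7 µU/mL", "roughly 15% below").

Three constants are fixed by inversion or explicit choice:

* $K_g$ (`derive_K_g()`): anchored by $g(100) = 6\times 10^{-4}$, giving
  $K_g \approx 4081.3$ mg/dL. A consequence worth checking: for the KPD
  phenotype ($k_{IN} = 71$/day) the inactivation rate at 150 mg/dL is
  $\approx 0.096$/day, i.e. roughly 10% of active cells per day.
* $K_h$: nothing observable pins it, because only the product $k_D h(G)$
  matters and $k_D$ is a per-patient phenotype. We set $K_h = 200$ mg/dL so
  that permanent death accelerates through severe hyperglycemia but stays
  slow (half-life of years) at mild fasting hyperglycemia, consistent with
  the months-to-years progression of conventional diabetes. The qualitative
  preset behaviours are verified in the tests for $K_h$ anywhere in
  100–250 mg/dL.
* $\beta_{TOT}$ and $c_{\max}$ appear only through their product, so
  $\beta_{TOT}$ is normalized to 1 and `calibrate_secretion()` solves the
  two steady-state conditions for the $c_{\max}$ that places the healthy
  fasting fixed point of each virtual patient at $G = 110$ mg/dL
  (mild fasting hyperglycemia, the advanced-prediabetes starting point).

The four virtual patients differ only in their glucotoxicity rates
(`kpd_preset()`): A, the conventional phenotype, $k_{IN} = 4.8$,
$k_{RE} = 0.04$, $k_D = 10^{-3}$; B, the remitting KPD phenotype,
$k_{IN} = 71$; C, KPD with slower reactivation, $k_{RE} = 0.028$; D, KPD
with fast permanent death, $k_D = 0.07$ (all per day). The calibration
target is applied to each preset separately: captions elsewhere describe B
as sharing all other parameters with A, but the governing statement is
that each phenotype presents with the same mild fasting hyperglycemia, so
the secretion scale is recalibrated per preset; both readings are
available through `update_parameters()`.

```{r}
fp <- find_fixed_points(kpd_preset("B")$params)
fp
```

The KPD phenotype is bistable at zero intake: a healthy state at
110 mg/dL, a hyperglycemic state near 837 mg/dL (no renal glucose
clearance is modelled, which inflates this value), and an unstable
threshold between them.

## Fixed points by polynomial root solving

With the fast pair $(G, I)$ equilibrated and death neglected, insulin is
slaved to secretion, $I = (\beta c f(G) + F_I)/\gamma$, and the reversible
cycle fixes $\beta = \beta_{TOT}/(1 + (k_{IN}/k_{RE})\,g(G))$. Substituting
both into the glucose balance and clearing the three rational denominators
(the hepatic term, $f$'s Hill denominator, and $g$'s Hill denominator)
yields a degree-9 polynomial in $G$; at fixed $\beta$ the same
construction yields a quintic (`fixed_point_polynomial()`). Roots are
computed as eigenvalues of the companion matrix. Numerical choices that
matter:

* Coefficients legitimately span ~20 orders of magnitude, so the variable
  is rescaled ($G = s x$ with $s = (|c_0|/|c_n|)^{1/n}$) before forming
  the companion matrix, followed by three Newton polishing steps.
* Candidate roots are kept when real to within $10^{-8}$ (relative),
  positive, at most 5000 mg/dL (no physical root can exceed
  $m_0/(S_E I_0) = 1200$ for canonical constants; the cap leaves margin for
  scans), verified against the *un-cleared* balance residual at relative
  tolerance $10^{-8}$, and deduplicated within $10^{-6}$ mg/dL.
* Stability is judged on the one-dimensional reduced flow
  $\dot\beta = -k_{IN} g(\hat G(\beta))\beta + k_{RE}(\beta_{TOT}-\beta)$
  by a central difference with relative step $10^{-6}$, mirroring the
  timescale separation; the full 4-D Jacobian is computed as a cross-check
  and disagreement raises a warning, not an error. The fast subsystem's
  equilibrium at fixed $\beta$ is asserted unique numerically on every
  call.
* In a bistable set the branch labels follow the glucose ordering. A
  monostable point carries no structural branch identity (the branches
  merge smoothly at low $k_{IN}/k_{RE}$), so it is labelled hyperglycemic
  only when its glucose exceeds a configurable 300 mg/dL threshold — the
  same proxy used for crisis annotation.

The whole pipeline is cross-checked in the tests against a dense sign-scan
of the steady-state residual (step 0.1 mg/dL over (0, 5000]) on 100
log-normally perturbed virtual patients; agreement is far below the
$10^{-4}$ mg/dL requirement.

`scan_1d()` sweeps intake $M$, infusion $F_I$, the inactivation ratio
$k_{IN}/k_{RE}$, $S_I$, or $\beta_{TOT}$, and refines every change in the
stable-root count by bisection to $10^{-4}$ relative tolerance — a robust
choice for a polynomial with well-separated roots, avoiding eigenvalue
tracking. For the KPD preset the healthy branch disappears at
$M \approx 245$ mg/dL/day, and an infusion of $F_I \approx 76$ µU/mL/day
removes the hyperglycemic branch: the two "pushes" of the toggle switch.
`phase_diagram()` classifies the $(S_I, \beta_{TOT})$ plane (relative
multipliers, default 0.5–1.5) with the quasi-static adaptation rule:
$c = c_{\max}$ unless fasting glucose would fall below $G_0$, in which
case $c$ is reduced so the fasting point sits exactly at $G_0$. Reported
glucose is uncapped; the conventional 130 mg/dL display cap is applied
only in `autoplot()`.

## Scenario simulation

`simulate_scenario()` integrates the full five-state system with deSolve's
Radau IIA method (a fifth-order stiff implicit Runge–Kutta scheme with
adaptive step control), relative tolerance $10^{-8}$ and absolute
$10^{-10}$. Meals are three one-hour boxcar pulses (07:00, 12:00, 19:00)
whose daily total is 3% of $R_{\mathrm{ref}}$ under normal eating and 70%
under the high-sugar condition — about three to four cans of soda per day
on the ~200 g/day whole-body reference flux. Only the daily totals are
physiologically meaningful; the boxcar shape is the simplest choice whose
discontinuities can be handled exactly, so every meal edge and segment
boundary is an integration breakpoint. Daily aggregates come from
trapezoidal quadrature of the dense output (5-minute grid). The
positivity of the state is checked after every piece rather than clipped
during integration: the model is positivity-preserving analytically, so a
violation indicates step failure.

Treatment policies: a constant infusion (defaulting to 1.5× the
saddle-node infusion found by `scan_1d()`, guaranteeing the healthy state
is the only attractor) or titration, implemented as state feedback
$F_I = \max(0, \gamma I^*(G_{\min}) - \beta c f(G_{\min}))$ that holds
fasting glucose at the floor. "Treat until well controlled" is
operationalized differently for the two: under a constant dose, 7
consecutive days with daily mean glucose below 110% of the healthy
fixed-point value; under titration glucose is clamped below that threshold
from day one, so the endpoint is instead expressed on the slow variable —
treatment stops when the active fraction reaches the healthy fixed-point
$\beta$ within the same 1% band used for remission timing. Event
annotation uses a 300 mg/dL daily-mean proxy for crisis (no ketone-body or
acid–base physiology is modelled), 130 mg/dL for control, 14 confirmed
insulin-free days for remission, and 7 sustained uncontrolled days for
relapse; relapse is anchored to the end of a treatment course so that a
failed remission (virtual patient D) is annotated as such.

Default segment durations (30-day baseline, 30-day high-sugar month)
follow the clinical narrative the model was built around and are plain
arguments, not constants. The problem sizes used in the test suite —
120–225-day courses for the four presets, 100 random patients for the
oracle checks — were chosen as the smallest runs that exercise every
regime of the model.

## The optimal insulin protocol

With glucose clamped at a floor $G_{\min}$ and no sugar intake, the
inactivation cycle is linear and solves exactly:
$$\frac{\beta(t)}{\beta_{TOT}} =
 e^{-(k_{RE}+k_{IN}g(G_{\min}))t}\!\left(\frac{\beta(0)}{\beta_{TOT}}
 - \frac{k_{RE}}{k_{RE}+k_{IN}g(G_{\min})}\right)
 + \frac{k_{RE}}{k_{RE}+k_{IN}g(G_{\min})}.$$
The maintenance insulin $I^*(G_{\min})$ is the positive root of the
quadratic obtained from the glucose balance at $dG/dt = 0$, and the dose
schedule $F_I(t) = \gamma I^* - \beta(t)\, c\, f(G_{\min})$ starts high
and decays exponentially, floored at zero once endogenous secretion
suffices. Remission time inverts the closed form for the first crossing
of the healthy fixed-point $\beta$. Two conventions needed fixing:

* An exponential never reaches its asymptote, so "reached" means within
  1% of the start-to-target gap.
* Whenever the treated asymptote $\beta_\infty(G_{\min})$ does not exceed
  the target — exactly the case $G_{\min} \ge$ the untreated healthy
  fasting glucose, 110 mg/dL for preset B — remission time is infinite.
  Targeting *below* the fixed point is what produces remission, and lower
  targets remit faster; the remission-time curve is continuous and
  strictly increasing on its finite domain and jumps to infinity at the
  boundary.

```{r}
remission_curve(c(85, 90, 95, 100), params = kpd_preset("B")$params)
```

## What the virtual patients do and do not show

The four presets reproduce the intended clinical courses: A rides out a
high-sugar month and returns to baseline; B switches to persistent severe
hyperglycemia and is restored by a ~4-week titrated course; C needs a
strictly longer course; D loses too much of the pool permanently and
relapses after any course. Passing these checks shows the *mechanism* is
implemented faithfully — it does not validate the model against patient
data. In particular: meals are boxcars, insulin action has no delay, there
is no renal glucose clearance (so the untreated hyperglycemic state sits
unrealistically high, near 840 mg/dL), no ketone-body physiology (crisis
is a glucose threshold), no hypoglycemia risk model ($G_{\min}$ is an
exogenous constraint), and the secretion-response shape does not adapt.
The virtual-patient sampler (`sample_virtual_patient()`) draws log-normal
parameter perturbations purely as test plumbing — no population
distribution is claimed.

Two further numerical notes. With meals on, the daily-mean glucose of the
calibrated KPD patient drifts from the fasting fixed point (110) toward a
with-meals quasi-equilibrium in the mid-120s over weeks; this is the
positive feedback amplifying a small mean intake near a fold, not
integrator drift (halving the tolerances moves daily means by far less
than 0.1 mg/dL). And with $k_D > 0$ the only true equilibrium is the empty
pool, so all fixed-point analysis is performed on the death-free reduced
system; long-horizon behaviour with death is simulation-only.
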