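---
title: "Minimax design of LC quadratures for AUC estimation"
author: "aucdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimax design of LC quadratures for AUC estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aucdesign)
```

## The estimation problem

The area under a concentration–time curve over a finite window,
$AUC = \int_{0}^{T} C(t)\,dt$ with $T = 24$ h throughout this package, is
the standard measure of drug exposure: it determines clearance after
intravenous dosing, and regulators compare formulations through AUC
ratios in bioequivalence studies.  In practice AUC is computed from a
small number of measured concentrations with a *linear-combination* (LC)
quadrature
$$\hat Q = \sum_{i=1}^{n} w_i \hat C(t_i),$$
where the $t_i$ (knots) are the sampling times and the $w_i$ (weights)
are fixed real numbers.  The trapezoid rule, Gauss–Legendre (GL) and
Clenshaw–Curtis (CC) rules, Lagrange and spline integration are all LC
members.  Two facts make the design of $(t, w)$ statistical rather than
purely numerical:

* the true curve is unknown — it follows a pharmacokinetic (PK) model
  $C(t,\theta)$ whose parameters $\theta$ are only known to lie in a box
  (if $\theta$ were known, AUC would be known and no sampling would be
  needed);
* measurements carry noise.  We assume a constant coefficient of
  variation: $\hat C_i = C(t_i,\theta)(1 + c_v \varepsilon_i)$ with
  independent zero-mean, unit-variance $\varepsilon_i$.  Only these two
  moments enter any formula; the noise distribution is otherwise
  irrelevant.

With quadratic relative loss the risk of a design at $\theta$ is
$$R_r(\theta) = \frac{c_v^2 \sum_i w_i^2 C_i^2 +
  \bigl[AUC(\theta) - \sum_i w_i C_i\bigr]^2}{AUC(\theta)^2},$$
a variance term plus a squared relative bias.  Relative (not absolute)
loss is used because an error of 10 units matters far more when the true
AUC is 50 than when it is 300, and because bioequivalence works on
ratios.  The minimax design solves
$$\min_{t, w}\; \max_{\theta \in \Theta}\; R_r(\theta),$$
the trapezoid variant minimizing over knots only, with weights
regenerated from the trapezoid formula.  Treating $\theta$ as boxed
rather than random is deliberately conservative: no prior distribution
or covariance matrix is needed, only plausible parameter ranges, which
is what a pilot study typically yields.

## The five models

`pk_model(1:5)` covers the standard limited-sampling situations; the
amplitude constants absorb dose, bioavailability and volume of
distribution and are treated as known.

| id | model | free parameters | fixed |
|----|-------|-----------------|-------|
| 1 | one-compartment, first-order absorption, single dose | $k_a, k_e$ | $A = 20$ |
| 2 | same, steady state over $\tau = 24$ h | $k_a, k_e$ | $A = 20$ |
| 3 | two-compartment iv bolus (biexponential) | $k_1, k_2, \alpha$ | $A_1 = 10$ |
| 4 | iv bolus, Michaelis–Menten elimination | $K_M, V_m$ | $C_0 = 10$ |
| 5 | first-order input, Michaelis–Menten elimination | $K_M, V_m, k_a$ | $A = 5$ |

Models 1–3 have closed-form concentration, AUC, gradients and Hessians.
Model 4 has no closed-form $C(t)$, but the Michaelis–Menten bolus obeys
the implicit relation $K_M \ln(C/C_0) + (C - C_0) = -V_m t$, which the
package solves by safeguarded Newton iteration (monotone in $C$, so the
solve is certain); the implicit-function theorem then gives exact
parameter derivatives, and the integral identity
$AUC = [K_M(C_0 - C_T) + (C_0^2 - C_T^2)/2]/V_m$ gives an exact AUC from
the terminal concentration alone.  Model 5 is integrated with
`deSolve::lsoda`, the state augmented with the forward sensitivities
$\partial C/\partial \theta$, the running integral and its parameter
derivatives, so one solve yields concentration, AUC and exact gradients.
Second derivatives of models 4–5 are central differences of those exact
gradients.

Default parameter boxes reproduce the published ranges.  For models 1–2
the box is intersected with $k_a \ge 2 k_e$ (configurable): absorption
is kept distinctly faster than elimination, which excludes the
flip-flop degeneracy $k_a = k_e$ where the single-dose curve — and its
AUC — collapses to zero, and which reproduces the published AUC minima
(56 and 58) exactly at the corner $k_e = \ln 2/4$, $k_a = 2 k_e$.  The
biexponential model's reference AUC minimum of 50 is *not* reproducible
from its printed ranges (the corner value of the closed form is 47.85);
`auc_range()` reports the computed value and the discrepancy is simply
documented here, not patched.

## How the optimizer works

**Inner level** (`max_risk`): maximize $R_r$ over the box.  The single
linear constraint is folded into a smooth reparameterization (the
constrained parameter's lower bound becomes a function of the others,
and its coordinate an interpolation variable $u \in [0,1]$), so the
search region is again a plain box and every iterate is feasible.
Multistart box-constrained ascent (`nlminb`, with analytic gradient and
— except for model 5 — analytic Hessian) runs from all box corners, a
deterministic Halton set of interior points, and the lattice local
maxima of a dense vectorized verification grid.  Near-optimal designs
equioscillate: their risk surface carries many near-equal local maxima
on narrow ridges, which is why *all* grid local maxima (not just the
best grid point) are polished, and why the final winner of a design
search is re-certified on a 400-per-axis grid for the closed-form
models.  The reported objective always equals
`relative_risk(quad, model, theta_star, cv)$value` exactly.

**Outer level** (`optimize_trapezoid`, `optimize_lc`): the max-function
is piecewise smooth and plain descent on it stalls as soon as two inner
maximizers tie.  The package instead uses progressive discretization
with a working set: a coarse parameter grid plus every inner maximizer
found so far defines a finite minimax problem, attacked by

1. a Lawson-type multiplicative-weight solve for the weights at fixed
   knots (iteratively reweighted least squares; each per-$\theta$ risk
   is a convex quadratic in $w$, so the weighted subproblem is a linear
   solve);
2. for the LC search, simplex descent over the knots with the weights
   re-solved at every trial knot vector; for the trapezoid search, a
   quasi-Newton descent of the smoothed (log-sum-exp) working-set
   maximum using exact envelope gradients — the derivative of the
   worst-case risk in a design variable equals the partial derivative
   of $R_r$ at the maximizer (Danskin), chained through the trapezoid
   weight map and the knot parameterization;
3. a full inner maximization of the trial design, which either
   certifies its worst case (search stops) or contributes a new working
   point (exchange).

Ordered knots are parameterized through positive increments
($t_k = T\,\mathrm{cumsum}(e^{x})_k / \mathrm{sum}(e^{x})$), which keeps
them sorted by construction; the bound $|x_j| \le 6$ keeps adjacent
knots at least $\sim 10^{-5}$ h apart and trapezoid weights
non-degenerate.  The last trapezoid knot is pinned to $T$; a linear
extrapolation to time zero (for models with $C(0) > 0$) is an LC-exact
weight correction of the first two knots,
$\Delta w_1 = t_1 + t_1^2/(2(t_2 - t_1))$,
$\Delta w_2 = -t_1^2/(2(t_2-t_1))$, and the extrapolated point does not
count as a sample.  Weights are unconstrained — optimal LC rules do use
negative weights.

Every candidate — including the untouched GL, CC, equispaced-trapezoid
and optimal-trapezoid starting designs — is scored with the same
full-strength inner maximization, and the best verified design is
returned.  Two consequences: the optimal LC objective can never exceed
the best baseline's under identical settings, and all searches are
bit-reproducible (no random number is drawn anywhere in the optimizers;
start sets are corners, Halton points and fixed schedules).

Design choices where the problem statement leaves room:

* *Sample size semantics.* $n$ counts sampled concentrations (knots):
  a "limited sampling" design with $n = 2$ means two blood draws.  The
  6-knot GL baseline under this reading reproduces the reference
  worst-case values to three digits at all three noise levels, which we
  regard as confirming it.
* *Algorithm choice.* The exchange scheme replaces one-shot SQP descent
  of the raw max-function; in our experiments descent alone stalled an
  order of magnitude above the achievable objective for the noise-free
  6-knot cell, while the exchange reaches (and for that cell improves
  on) the reference values.  This is an algorithmic mitigation of
  exactly the "found solution may be suboptimal" hazard inherent to
  nested minimax problems.
* *Tie-breaking.* With several equal inner maximizers the envelope
  gradient is taken at the first one found in the fixed evaluation
  order; because the outer method is a working-set exchange, ties
  ultimately enter the working set anyway.
* *Noise in the simulator is Gaussian*, matching the reference
  evaluation protocol, but the risk formulas use only the first two
  moments.  Simulated negative concentrations are kept: truncation
  would break the zero-mean assumption behind the moment formulas.
* *Bias and deviances.* Bias is reported on the absolute scale,
  mean$(\hat Q - AUC)$, and the extreme deviances are reported signed
  (the signed error of largest magnitude), matching the reference
  tables' conventions.

## Tunable parameters

| parameter | meaning | default |
|---|---|---|
| `cv` | noise coefficient of variation (dimensionless) | 0, 0.05, 0.10 in the benchmark grid |
| `n` | number of sampled concentrations | 2, 4, 6 in the benchmark grid |
| `inner_starts` | Halton interior starts of the inner ascent | 16 |
| `grid_points` | verification grid per axis | 150 (2 parameters), 40 (3), 6 (model 5) |
| `exchange_rounds` | working-set exchange iterations | 4 |
| `nm_iterations` | simplex budget of the knots stage | 2000 (closed-form), 120 (model 5) |
| `lawson_iterations` | weight-solve iterations | 80 |
| `rtol` / `final_rtol` | ODE tolerance in search / verification | 1e-8 / 1e-10 |

The ODE tolerances follow the usual two-tier pattern: loose enough for
speed inside optimizer loops, tight for anything that is reported.

## What the simulator emulates — and what it does not

`simulate_profiles` draws $\theta$ uniformly over the feasible box
(rejection sampling under the $k_a \ge 2k_e$ constraint), evaluates the
exact model concentrations at the design's knots and applies
independent constant-CV Gaussian noise.  A uniform parameter
distribution deliberately scans the whole box — including the corners
where the worst cases live — making it a harder test than the
log-normal population distributions typical of real cohorts.  The
generator does *not* emulate: between-occasion variability,
correlated or time-dependent measurement error, model misspecification
(a patient following none of the five models), dosing-history errors,
or sampling-time deviations.  A passing simulation therefore certifies
the estimator under the stated model-and-noise assumptions, not against
structural model error.

Two inequalities connect simulation to optimization and are checked by
`consistency_checks`: RMSRE over profiles drawn inside the box must stay
below $\sqrt{\mathrm{Obj}}$ (the root worst-case risk), and in the
noise-free case every relative deviance — in particular the extreme
one — is bounded by $\sqrt{\mathrm{Obj}}$; a violation would mean the
inner maximization missed the true worst case.  With noise the second
bound may legitimately reverse.

## Numerical choices and degenerate inputs

* Model-4 Newton solve: monotone bracket $(0, C_0]$, damped steps,
  convergence at $10^{-13}$ relative; failure raises an explicit
  integration error naming the model and parameters.
* `auc_range`: 100 grid points per axis for 2-parameter models, 40 for
  3-parameter models, then gradient polish from the best grid points —
  deterministic, no randomness anywhere.
* Degenerate (point) boxes are legal everywhere and reduce `max_risk`
  to a single risk evaluation.
* A quadrature must have strictly increasing knots inside the interval;
  trapezoid kinds additionally pin the last knot to $T$.
* The certified objective of an essentially optimal noise-free design
  is accurate to about $10^{-4}$ relative: the maximum of an
  equioscillating design is locally flat, and polishing beyond that
  level is limited by the curvature of the ridge, not by the grid.

## Problem sizes used by the shipped tests

The test-suite uses reduced, fixed problem sizes chosen to exercise
every claim at desk scale: Monte-Carlo agreement of the risk formulas
at $10^5$ replicates (50 random cases, 3-standard-error bands),
simulation statistics at 2,000 profiles, the full benchmark sweep of
all 45 (model, $n$, $c_v$) cells with a reduced optimizer budget, and
the reference cell (model 1, $n = 6$, $c_v = 0$) at full optimizer
strength.  The package defaults reproduce the full-scale protocol
(20,000 profiles, full multistart) via `run_tables(...,
n_profiles = 20000)`.

## Known limitations

* Only the quadratic absolute and relative losses are implemented; no
  asymmetric or log-scale losses.
* Non-linear quadratures (log-trapezoid and relatives) are out of
  scope: their risk depends on the full noise distribution, not just
  two moments.
* The infinite-interval AUC (extrapolation to $t = \infty$) is not
  treated; the finite window is the natural target at steady state.
* Optimality is certified against a dense grid plus multistart ascent,
  not by a global-optimality proof; for the shipped 2–3 parameter
  boxes this is effectively exhaustive, but exotic user-supplied models
  with many parameters would need a denser verification grid.
* The box describes parameter uncertainty only; it cannot express
  correlations between parameters beyond single linear inequalities.
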