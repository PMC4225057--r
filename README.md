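# aucdesign

Minimax-optimal sampling designs and quadratures for estimating the
area under a pharmacokinetic concentration–time curve (AUC) from sparse,
noisy measurements.

## The problem

AUC over a finite window, `AUC = ∫₀²⁴ C(t) dt`, measures drug exposure;
it drives clearance estimates and bioequivalence decisions.  With only
`n = 2–6` blood samples, AUC is estimated by a *linear-combination (LC)
quadrature*

    Q̂ = Σᵢ wᵢ Ĉ(tᵢ),

with sampling times `tᵢ` (knots) and fixed real weights `wᵢ`.  The
trapezoid rule, Gauss–Legendre (GL) and Clenshaw–Curtis (CC) are all LC
members.  Choosing the design is a statistical problem because the PK
parameters `θ` are only known to lie in a box `Θ`, and measurements
carry constant-CV noise, `Ĉᵢ = C(tᵢ, θ)(1 + c_v εᵢ)`.  Under quadratic
relative loss the risk at `θ` is

    R_r(θ) = { c_v² Σᵢ wᵢ² C(tᵢ,θ)² + [AUC(θ) − Σᵢ wᵢ C(tᵢ,θ)]² } / AUC(θ)²

and the package solves the minimax design problem

    min over (t, w)  of  max over θ in Θ  of  R_r(θ)

for five standard concentration–time models (one- and two-compartment
linear kinetics; Michaelis–Menten elimination with bolus or first-order
input), alongside the optimal-trapezoid, GL and CC baselines evaluated
under the same worst-case criterion, and a Monte-Carlo evaluation
harness.  It is aimed at pharmacometricians developing limited-sampling
strategies, and more generally at anyone estimating integrals from few
noisy samples of a parametric curve family.

## Worked example

Design a 6-sample trapezoid schedule for the single-dose
first-order-absorption model (A = 20, `ka ∈ [ln2/4, 3ln2]`,
`ke ∈ [ln2/12, ln2/4]`, `ka ≥ 2ke`), without measurement noise, and
check it by simulation:

```r
library(aucdesign)

m1  <- pk_model(1)
box <- default_box(1)

max_risk(gauss_legendre(6), m1, box, cv = 0)$sqrt_objective
#> [1] 0.01899                # worst-case relative error of plain GL-6

tr <- optimize_trapezoid(m1, box, cv = 0, n = 6)
tr
#> Minimax design (trapezoid), model 1, n = 6, cv = 0
#> LC quadrature (trapezoid), n = 6 on [0, 24]
#>   knots:   0.316945, 2.16913, 4.97381, 8.46049, 13.1919, 24
#>   weights: 0.926091, 2.32843, 3.14568, 4.10904, 7.76975, 5.40406
#>   worst-case theta: ka = 0.173287, ke = 0.0577623
#>   objective = 0.000222488  sqrt = 0.01492

st <- evaluate_method(tr$quadrature, m1, box, cv = 0,
                      n_profiles = 2000, seed = 1)
st
#> Monte-Carlo evaluation (2000 profiles, cv = 0)
#>   bias: -0.9861   RMSRE: 0.008545
#>   extreme deviance: -3.691 (absolute), -0.01485 (relative)

consistency_checks(st, tr)[, c("check", "passed")]
#>                                                      check passed
#> 1                                  rmsre < sqrt(objective)   TRUE
#> 2 max |relative deviance| <= sqrt(objective) [cv = 0 only]   TRUE
```

Reading the numbers: the optimized schedule samples densely early
(where the curve bends) and guarantees a worst-case relative
quadrature error of 1.49% over the whole parameter box, versus 1.90%
for Gauss–Legendre with the same six samples.  The simulation confirms
the guarantee — the root-mean-squared relative error (0.85%) and even
the single worst of 2,000 noise-free profiles (1.485%) stay below the
certified bound, as they must when the inner maximization succeeded.
Freeing the weights as well (`optimize_lc(m1, box, cv = 0, n = 6)`)
drives the worst-case error below 1e-6: with twelve free design
parameters against two model parameters, the noise-free quadrature
problem is essentially solvable.  With realistic noise
(`cv = 0.05–0.10`) the gap between methods narrows and the variance
term dominates — the regime where method choice matters most is sparse
sampling at low noise.

The same machinery is scriptable:

```sh
Rscript inst/cli/aucquad.R optimize --model 1 --n 6 --cv 0 --method lc \
        --seed 1 --out design.json
Rscript inst/cli/aucquad.R evaluate --design design.json --profiles 20000
Rscript inst/cli/aucquad.R tables   --models 1,2,3,4,5 --profiles 20000 \
        --out tables.csv
Rscript inst/cli/aucquad.R auc-range
```

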