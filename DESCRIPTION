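Package: aucdesign
Title: Minimax-Optimal Sampling Designs and Quadratures for AUC Estimation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design of linear-combination (LC) quadratures Q = sum(w_i C(t_i))
    that estimate the area under a pharmacokinetic concentration-time curve
    from a small number of blood samples.  Implements five standard
    concentration-time models (one- and two-compartment linear kinetics,
    Michaelis-Menten elimination with bolus or first-order input) with exact
    AUC and first- and second-order parameter sensitivities; the worst-case
    (minimax) relative-risk criterion under constant coefficient-of-variation
    measurement noise; nested inner-outer optimization of sampling times and
    weights; classical baselines (optimal trapezoid with linear extrapolation
    to time zero, Gauss-Legendre, Clenshaw-Curtis); and Monte-Carlo
    evaluation of any design against a parameter box.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
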