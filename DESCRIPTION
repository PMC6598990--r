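Package: sddcell
Title: Stability Analysis of a State-Dependent Delay Model of Stem-Cell
    Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the equilibrium and stability analysis of a
    stem-cell maturation model formulated as a differential equation with
    threshold-type state-dependent delay.  The delay is the time a
    progenitor cell needs to mature across a continuous maturity interval,
    and is defined implicitly through an ordinary differential equation
    for the maturity variable.  The package evaluates the model rates and
    their derivatives, computes threshold delays and trajectories, locates
    trivial and positive equilibria, evaluates characteristic equations
    and localises their roots by the argument principle, provides the
    closed-form stability boundary for the fixed-delay special case,
    implements the time transformation that converts the model to a
    fixed-delay system when the maturation rate is independent of
    maturity, and reduces the delay equation to a finite system of
    ordinary differential equations by pseudospectral (Chebyshev)
    collocation whose Jacobian eigenvalues approximate the characteristic
    roots.  Stability boundaries in parameter planes can be traced
    numerically and cross-validated between the analytic, pseudospectral
    and time-transformed routes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
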