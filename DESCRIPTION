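Package: osteoremod
Title: Cell-Mechanobiological Simulation of Cortical Bone Remodeling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates load-driven cortical-trabecular bone remodeling in an
    idealized long-bone diaphysis. An axisymmetric finite-element elasticity
    solver with a density-dependent Young's modulus (E = E0 * rho^2) supplies
    the elastic strain energy that drives a four-parameter osteoblast /
    osteoclast activity law with homeostatic, formation and overload-resorption
    energy thresholds. Cell activity is modulated by a (alpha - rho)^n
    intensity law across the cortical-trabecular interface and integrated in
    time with an explicit staggered coupling, with optional first-order
    activation delay. Includes scenario presets for sedentary, intermittent-
    and continuous-running loading, parameter-identification utilities from
    cortical-thickness observations, radial profile and remodeling-front
    summary metrics, synthetic density-profile fixtures, CSV/VTK export and a
    small command-line driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
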