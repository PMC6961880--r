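Package: whealdyn
Title: Reaction-Diffusion Dynamics of Histamine Release and Wheal Formation in Urticaria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single reaction-diffusion equation for histamine released
    by dermal mast cells, with self-activation limited by a finite intracellular
    histamine store, dose-dependent self-inhibition, and a hysteretic threshold
    readout of the visible wheal. Provides the space-free kinetic analysis
    (equilibria, stability, pattern-regime conditions, analytic traveling-wave
    speed bound), a zero-flux explicit finite-difference solver on 2-D grids and
    an axisymmetric radial reduction, wheal-front tracking and expansion-speed
    estimation, morphological classification of simulated wheal masks, and the
    intradermal-injection analytics: the point-source diffusion solution, wheal
    radius and velocity curves, saturating-exponential regression, and a
    multi-dose diffusion-coefficient estimation workflow with a synthetic
    clinical-series generator.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    minpack.lm,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
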