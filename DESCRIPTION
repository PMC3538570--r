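Package: ftkin
Title: Fourier-Domain Closed-Form Estimation of Two-Tissue Compartment
    Model Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracer kinetic modelling in dynamic emission
    tomography with the reversible two-tissue compartment model.
    Implements a frequency-domain closed-form estimator for the four
    rate constants (K1, k2, k3, k4) that uses only the low-frequency
    discrete Fourier components of the blood input and tissue
    time-activity curves, enforcing the DC-gain (volume of
    distribution) relation as a hard constraint, so no initial guess
    is required.  Includes the analytic bi-exponential forward model,
    a Feng-type arterial input simulator with non-uniform frame
    schedules and count-statistics noise, weighted nonlinear
    least-squares refinement of the closed-form estimate, delimited
    text input/output for measured curves, a Monte-Carlo experiment
    harness, and a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
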