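Package: kbident
Title: Identifiability of Stiffness-Damping-Inertia Models of Joint Impedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation study of joint impedance identification with
    second-order stiffness-damping-inertia (KBI) models. Provides a
    third-order linearized musculoskeletal plant (a segment driven by a
    Hill-type muscle with a visco-elastic contractile element in series
    with an elastic tendon), exact zero-order-hold simulation of its
    torque-perturbation responses, Nelder-Mead fitting of KBI parameters
    to those responses, closed-form low- and high-frequency approximations
    of the fitted parameters, Hessian-based sensitivity of the estimates
    to measurement error, and full-factorial parameter sweeps with
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
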