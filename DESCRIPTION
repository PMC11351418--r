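Package: liftopt
Title: Predictive Simulation of Human Lifting with Powered Exoskeletons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for predictive simulation of sagittal-plane squat lifting
    by a 10-degree-of-freedom Denavit-Hartenberg skeletal model coupled with
    one-degree-of-freedom powered exoskeletons at the knee, spine, and
    shoulder.  Joint torques are computed by recursive Lagrangian inverse
    dynamics with analytic sensitivities; joint-angle and motor-current
    trajectories are parameterized by clamped cubic B-splines and optimized
    by sequential quadratic programming subject to joint-limit, torque-limit,
    zero-moment-point stability, and task constraints.  Includes DC-motor
    electromechanical models of the assistive devices, ground-reaction-force
    and mechanical-energy reporting, and least-squares fitting of
    torque-versus-angle controller maps for real-time assistance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
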