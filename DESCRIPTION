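Package: wallswim
Title: Guidance of a Microswimmer by Wall-Generated Oscillatory Flow
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model and control toolkit for a spherical microswimmer moving
    above an active wall (e.g. a magnetic cilia carpet) that generates a
    travelling-wave flow with a controllable amplitude. Implements the
    far-field wall flow and equations of motion, optional squirmer-wall
    hydrodynamic interaction, local controllability analysis along
    free-swimming reference trajectories via a time-varying Kalman-type
    condition, closed-form transport estimates (characteristic flow speed,
    switch period, flow gain, minimal transit time, velocity boost),
    time-optimal bang-bang control solvers for wall-parallel displacement,
    reorientation and wall-distance change, and open-loop versus feedback
    driving policies with transport and robustness metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
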