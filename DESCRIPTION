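Package: smcollide
Title: Stochastic Simulation and Inference of SMC-Replisome Collisions on
    Circular Bacterial Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of replisome progression and SMC
    loop-extrusion dynamics on a circular bacterial chromosome under
    programmable experimental protocols (temperature-gated initiation,
    inducer-gated SMC loading, polymerase-inhibitor fork stalling), with
    forward models for marker frequency analysis (MFA) tracks, ChIP-like
    occupancy profiles and Hi-C contact maps, and the inference machinery
    used to study SMC-replisome collisions: competing-risk collision
    kinetics (blocking, unloading, bypassing), fork-memory slowdown of
    loop extruders behind moving forks, kinetic estimators, and
    goodness-of-fit parameter sweeps. Includes a synthetic-data generator
    with known ground truth for every scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
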