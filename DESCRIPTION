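Package: uwheel
Title: Magnetic Microwheel Swarm Physics and Vascular Targeting Simulation
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the rolling of magnetically actuated colloidal microwheels
    (spinning clusters of superparamagnetic beads) on inclined surfaces using a
    wet-friction force balance with a variable lubrication gap width set by
    electrostatic repulsion against the normal load. Builds on the
    single-wheel model to represent multimodal microwheel swarms as per-wheel
    radius/velocity/mass distributions, predicts time-dependent mass transport
    and centroid velocities, and simulates swarm targeting through branching
    vascular-like networks by Euler integration with mass-weighted centroid
    steering and sigma-window clipping at turns. Includes fluorescence-scan
    quantification of targeting efficiency (16-bit threshold, beads-per-count
    calibration, ROI division) and a synthetic-data generator producing
    swarms, networks and scan pairs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
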