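Package: elbowsim
Title: Anatomically Constrained Musculoskeletal Simulation of the Elbow Joint
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multibody simulator of the human elbow in which the joint is not a
    mechanical hinge but is constrained by tension-only nonlinear ligament bundles,
    frictionless deformable cartilage contact discretized into 3 x 3 mm elements, and
    muscle actuators driven by PCSA-scaled PID controllers. Implements the two-phase
    protocol used to evaluate such models: kinematic replay of a motion trial to record
    muscle-length targets (inverse kinematics), followed by muscle-driven forward
    dynamics of the free forearm bones. Includes anatomical six-degree-of-freedom
    kinematic decomposition, RMS-error and correlation evaluation, EMG envelope
    processing, and a deterministic synthetic-subject generator (parametric bone and
    cartilage geometry, laxity sweeps, isokinetic and fast flexion trials, surrogate
    EMG) so the full pipeline runs without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
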