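Package: colonyraft
Title: Contour-Thrust Raft Model and Trajectory Analysis for Bacterial
    Motion at the Air-Liquid Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the motion of Escherichia coli microcolonies
    ("rafts") trapped at an air-liquid interface with an overdamped
    rigid-body model in which only the bacteria on the colony contour
    thrust, with quenched random force angles.  Derives steady-state
    speed, signed angular velocity and radius of curvature, predicts
    their power-law scaling with colony size, and provides the companion
    trajectory-analysis pipeline: track filtering, tumble-cusp arc
    segmentation, dual (algebraic plus geometric) least-squares circle
    fitting with coherence rejection, handedness classification,
    marker-pair rigid-body kinematics and population statistics.  A
    synthetic-data module generates run-and-tumble swimmer tracks and
    rigid raft marker tracks with ground truth, calibrated to published
    population means, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
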