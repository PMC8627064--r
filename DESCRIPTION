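Package: rehabtrack
Title: Markerless Upper-Limb Tracking and Virtual Rehabilitation Task
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational core of a two-camera markerless upper-limb
    tracking pipeline for virtual-reality rehabilitation. Synthesizes
    dual-camera 2D keypoint streams of reaching, mirrored and grasping
    motions, reconstructs and smooths 3D joint trajectories by stereo
    triangulation and One-Euro filtering, retargets them onto an avatar
    skeleton with finger forward kinematics and analytic two-bone arm
    inverse kinematics (including a mirrored contralateral mode), runs
    the three rehabilitation task paradigms as deterministic clock-driven
    trial state machines, and computes the movement outcome measures:
    per-trial score from the mean hand-to-line distance, game
    performance, wrist velocity peaks and the unfinished rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
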