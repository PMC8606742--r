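Package: momentarms
Title: Geometric Muscle Moment Arms, Joint Kinematics and Range-of-Motion
    Envelopes from Marker-Based Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for marker-based musculoskeletal kinematics and muscle
    leverage analysis. Implements joint-coordinate-system kinematics from
    rigid-body transforms (orthogonal Procrustes marker fits, Euler
    decomposition, zero-phase low-pass filtering), signed per-axis muscle
    moment arms computed geometrically as the common perpendicular between a
    joint axis and a straight muscle line of action, an independent
    tendon-travel estimator for cross-validation, pooled range-of-motion
    summaries and cosine-corrected alpha-shape pose-space envelopes with
    volumes, and a PCSA-based Hill-type isometric torque layer. A synthetic
    two-bone joint-rig simulator with analytic ground truth supports
    end-to-end validation, and a small command-line front-end ties the
    pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
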