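Package: kneeload
Title: Static-Optimization Simulation of Muscle Coordination and Knee Contact Force
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates muscle coordination during walking with per-timestep
    static optimization over a sagittal-plane lower-limb model: Hill-type
    musculotendon actuators with a compliant tendon, moment-matching
    constraints, a natural (sum of squared activations) and a gastrocnemius
    avoidance objective, and optional EMG-derived activation-ratio
    constraints. Computes knee contact force along the tibia axis and
    decomposes it into intersegmental and muscle-group contributions.
    Includes surface-EMG linear-envelope processing with MVC normalization
    and electromechanical delay, the gastrocnemius-to-soleus activation-ratio
    biofeedback metric with its adaptive target rule, and a seeded synthetic
    gait generator with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    quadprog,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
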