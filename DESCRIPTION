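Package: dualadapt
Title: Dual-Error Learning Models of Visuomotor Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and trial-by-trial fitting of a dual-error model of
    reach adaptation under visuomotor rotation. A scalar Kalman filter
    estimates the imposed perturbation from sensory prediction errors while
    an actor-critic policy, driven by temporal-difference reward prediction
    errors and active search noise, adjusts the motor command directly.
    Includes generators for the standard gradual-rotation paradigms
    (continuous-cursor, endpoint-only and reward-only feedback), a synthetic
    subject and cohort generator with proprioceptive localization and
    generalization probes, a constrained dual-memory state-space fit that
    decomposes each subject's reach series into sensory- and reward-driven
    components, and the behavioral indices (adaptation, reach variability,
    illusion index, generalization index) used to compare feedback
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
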