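Package: ctrleffort
Title: Control Effort of Closed-Loop Movements via Information-Minimal
    Signal Discretization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the control effort of a closed-loop movement: the
    minimal information, in bits, that the control signals of a system must
    carry for the movement to still satisfy its performance criterion.
    Control signals are discretized in amplitude and time; their information
    content is measured with Shannon entropy, and the coarsest feasible
    resolution is found with a three-phase pattern search tailored to a
    cheap monotone cost and an expensive Boolean simulation constraint.
    Ships small muscle-like and torque-driven one-degree-of-freedom plants
    with pointing and periodic locomotion-like tasks so that biological
    (muscle) and technical (ideal torque) actuation can be compared
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
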