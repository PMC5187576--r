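Package: flocculus
Title: Cerebellar Network Model for Closed-Loop Adaptive Motor Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Firing-rate model of the cerebellar cortical microcircuit
    (granule, Golgi, basket/stellate and Purkinje cells) with
    climbing-fiber-gated plasticity at parallel fiber-Purkinje synapses,
    embedded in a closed control loop beside a proportional-derivative
    controller.  Simulates two control plants (a DC motor shaft and a
    two-wheeled balancing robot) and compares candidate climbing-fiber
    teaching signals (sensory error, motor error, and their linear
    combination) by tracking performance, long-term depression and
    potentiation statistics, and granule-cell correlation profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
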