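Package: divasim
Title: In Silico Closed-Loop Vasopressor Delivery for Spinal Hypotension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for closed-loop vasopressor delivery during
    spinal anesthesia for cesarean delivery. Implements two automated
    bolus-dosing controllers (ADIVA and DIVA) that band beat-to-beat systolic
    blood pressure against a pre-anesthesia baseline, select phenylephrine or
    ephedrine by heart rate, and modulate delivery speed by the least-squares
    blood-pressure trend; a seeded virtual-patient hemodynamic generator with
    spinal-block hypotension and effect-site bolus pharmacodynamics; pooled
    performance-error statistics (MDPE, MDAPE, wobble, divergence) and
    hemodynamic outcome summaries; and a two-arm in-silico trial runner with
    the associated two-proportion sample-size calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
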