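Package: cmgraft
Title: Design and Analysis of Compliance-Matching Multi-Layer Aortic Stent-Grafts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing multi-layer aortic stent-grafts that match the
    distensibility of healthy human aortas. Provides constitutive models for
    woven PET graft fabric (third-order Ogden hyperelasticity) and superelastic
    nitinol z-stents (one-dimensional flag-shaped hysteresis with
    Clausius-Clapeyron temperature shifts), a reduced-order axisymmetric
    pressure-radius evaluator for the two-layer assembly, iterative 6-factor
    Box-Behnken response-surface optimization of the stent geometry toward a
    target aortic distensibility, and a bench-data pipeline that turns hydraulic
    circuit recordings (pressure, pump flow, external diameter) into volume and
    area compliance and distensibility, including low-pass filtering, cycle
    segmentation, beam-bending volume correction and the study statistics.
    Seed-deterministic synthetic generators emulate uniaxial tensile tests and
    bench recordings with known ground truth so every stage is testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    lhs,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
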