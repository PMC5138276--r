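Package: neckcool
Title: Lumped-Parameter Thermal Modelling of Selective Brain Cooling via a Neck Collar
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates selective brain cooling induced by a wearable cooling
    collar applied to the neck. The head, neck and body are modelled as lumped
    thermal compartments coupled by a circulating blood loop; collar heat
    extraction, steady-state settling, two-phase cooling protocols, and
    cooling-rate estimation are implemented for sheep and human parameter
    sets. Includes a synthetic generator of experiment-like 1 Hz brain/body
    temperature recordings, the associated small-sample statistical pipeline
    (moving-average summaries, Shapiro-Wilk normality screening, paired t
    tests), and bounded least-squares calibration of under-determined model
    parameters against temperature recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
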