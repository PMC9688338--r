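Package: gswnet
Title: Interictal EEG Network Analysis of Generalized Spike-Wave Discharges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for interictal scalp EEG network analysis of
    generalized spike-wave discharges (GSWDs): Butterworth filtering and
    common-average referencing, global-field-power spike-event detection and
    epoch extraction, sLORETA source estimation on a supplied lead field,
    imaginary-part-of-coherence functional connectivity at 1-12 Hz,
    network-based-statistic permutation inference on paired GSW versus
    resting-state connectivity, weighted small-world propensity with lattice
    and random null models, and integrated-value-of-influence hub
    identification.  A seeded synthetic-cohort generator with known ground
    truth (planted spike events and phase-lagged source couplings) supports
    validation in the absence of public patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    igraph,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
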