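Package: anestherm
Title: Thermoregulation and Anesthesia Depth Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the interaction between core body temperature
    and isoflurane anesthesia depth in rodents. Provides a synthetic cohort
    generator (core-temperature relaxation dynamics, burst-suppression EEG,
    fiber-photometry transients, righting-reflex event logs), EEG spectral
    band-power and burst-suppression-ratio computation, fiber-photometry
    dF/F and Z-score processing with peri-event alignment, the regression
    models used in this literature (linear ambient-vs-core temperature,
    one-phase exponential decay of emergence latency versus core temperature,
    and a segmented breakpoint model for the emergence-latency inflection),
    and between-group model comparisons via extra-sum-of-squares F tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
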