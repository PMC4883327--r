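Package: rosenose
Title: Electronic-Nose Quality Classification of Rose Essential Oils
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Chemometrics pipeline for qualitative classification of Rosa
    damascena essential oils from metal-oxide-semiconductor (MOS) electronic-nose
    sensor arrays. Assigns reference quality classes from GC-MS constituent
    tables (six key volatiles, 10%/50% thresholds), extracts seven
    steady-state and kinetic features per sensor transient, ranks features by
    the Fisher (intra/inter variance) ratio, and compares a from-scratch
    Fuzzy ARTMAP adaptive-resonance classifier against multiclass linear
    discriminant analysis under leave-one-out cross-validation. Includes a
    synthetic generator of seven-sensor MOS transients with first-order
    rise/recovery kinetics for fully reproducible end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
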