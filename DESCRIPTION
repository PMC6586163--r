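Package: rootprobe
Title: Root Pressure-Probe Transport Analysis and Suberin Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and inverse estimation for root
    pressure-probe experiments under the composite transport model of
    radial water and solute flow: hydraulic conductivity (Lpr), solute
    permeability (Psr) and the reflection coefficient (sigma) are
    recovered from hydrostatic pressure relaxations and biphasic osmotic
    responses.  Also provides PEG-8000 osmoticum calibration (water
    potential from mass fraction), zone-resolved suberin monomer
    quantification normalized to endodermal surface area, one-way ANOVA
    with Fisher LSD compact letter displays, TPM expression summaries,
    and seeded synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
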