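Package: stripesignal
Title: Visual Modeling and Behavioral Analysis of Dynamic Color Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying honest visual signals in fish along a
    three-stage framework: receptor-noise-limited visual modeling of
    color-pattern conspicuousness under depth-attenuated underwater light,
    dyadic-contest analysis linking a dynamic melanic stripe signal to
    dominance, and out-of-equilibrium manipulation analysis quantifying
    social punishment of unreliable signalers. Includes seeded synthetic-data
    generators emulating facial patch reflectance spectra, a trichromatic
    plus luminance fish visual system, staged contests, and mirror-image
    stimulation trials, so every stage of the pipeline is testable without
    access to the original measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    multcomp,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
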