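Package: btbimech
Title: Blast-Induced Traumatic Brain Injury Mechanics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale mechanics toolkit for primary blast-induced
    traumatic brain injury (bTBI). Provides finite-strain
    hyperelastic-viscoelastic constitutive models for grey and white brain
    matter (the white-matter model incorporating axonal fibre orientation
    and fractional anisotropy from diffusion-tensor data), a set of
    candidate mechanistic injury criteria including power-based shear and
    axonal energy-rate criteria with calibrated damage thresholds, a
    scaled-distance blast overpressure generator with Friedlander waveforms,
    an explicit one-dimensional Lagrangian wave solver for layered
    shield/skull/CSF/brain columns, a protective-shield design sweep over
    acoustic-impedance and wave-speed ratios, and a region matching-accuracy
    scorer for comparing predicted against experimentally labelled damaged
    brain regions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
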