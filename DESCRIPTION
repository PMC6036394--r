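Package: mplocate
Title: Source Position Verification for HDR Brachytherapy with a 2D Diode Array
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction pipeline for verifying the dwell
    positions of an Ir-192 high-dose-rate (HDR) brachytherapy source with a
    couch-embedded 11x11 diode array. Provides an analytic TG-43U1 dose-rate
    model (line-source geometry function, radial dose function, 2D anisotropy
    function), synthetic voxel phantoms (uniform water and a heterogeneous
    pelvic-like geometry with bone, gas and a carbon couch), a virtual diode
    array forward model with water-equivalent path-length attenuation scaling
    and measurement noise, dose-to-distance inversion with iterative
    multilateration including angular-dependence and CT-density corrections,
    and a study driver that quantifies per-axis localization accuracy across
    detector subset sizes with Student's t-tests and one-way ANOVA.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
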