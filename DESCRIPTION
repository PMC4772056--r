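Package: oilnmr
Title: Automated Fatty Acid Composition Screening of Edible Oils by 1H-NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated screening pipeline for the fatty acid composition of
    edible oils from 1D 1H-NMR spectra acquired at low field (300 MHz).
    Reads raw Bruker datasets (binary 'fid' plus 'acqus' parameter file),
    applies Fourier transformation with zero filling, automatic phase
    correction by entropy minimization, asymmetric-least-squares baseline
    correction and TMS referencing, integrates the ten assigned oil signal
    regions (A-J) with a temperature-tracked water exclusion, and reports
    saturated, mono-unsaturated and poly-unsaturated fatty acid percentages,
    the iodine value estimated from the olefinic proton percentage, and the
    F/H triglyceride validity ratio. A synthetic oil-spectrum generator with
    known ground-truth composition (Lorentzian lineshapes, 13C satellites,
    temperature-dependent residual water, seeded noise) makes every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
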