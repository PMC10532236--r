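Package: iohexolGFR
Title: Measured Glomerular Filtration Rate from Plasma Iohexol Clearance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for laboratory workflows that measure glomerular
    filtration rate (GFR) from the plasma clearance of iohexol quantified
    by LC-MS/MS. Implements internal-standard calibration with back-fit
    and quality-control acceptance rules, three-point slope-intercept
    clearance with the Brochner-Mortensen correction and body-surface-area
    normalization, a full clinical method-validation statistics battery
    (limits of detection and quantification, precision, carryover,
    recovery, matrix effect, stability, Deming regression, Bland-Altman
    agreement), CSV-based batch and result-file handling for laboratory
    information systems, and a two-compartment pharmacokinetic simulator
    that provides synthetic instrument batches with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
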