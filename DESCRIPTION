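Package: oofrecon
Title: Out-of-Field Response Correction for Measurement-Guided 3D Dose
    Reconstruction QA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for patient-specific IMRT/VMAT quality assurance built
    around an out-of-field (OOF) detector response correction for
    measurement-guided 3D dose reconstruction on cylindrical diode arrays.
    Accumulates MU-weighted beam's-eye-view fluence from MLC/jaw control
    point sequences, builds per-subbeam composite OOF correction masks,
    and applies them to 3D dose grids with divergent projection and
    surface taper.  Includes gamma-index analysis with global and local
    dose-error normalization, TG-119-style confidence-limit statistics,
    a synthetic plan/dose/detector simulator with tabulated diode
    response perturbations (low-MU nonlinearity, dose per pulse,
    repetition rate, out-of-field overresponse), and a tuning procedure
    that selects the OOF correction factor against a reference
    measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
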