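Package: atnquant
Title: Regional PET Quantification, Centiloid/CenTauR Calibration and
    A/T2/N Biomarker Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification core for amyloid- and tau-PET studies of
    Alzheimer's disease. Extracts regional standardized uptake value
    ratios (SUVr) from co-registered PET and anatomical label volumes in
    NIfTI-1 format, converts them to the harmonized Centiloid (CL) and
    CenTauRz (CTRz) scales via bundled and user-fitted cross-tracer
    linear calibrations, scores neurodegeneration from structure volumes,
    and assigns categorical A/T2/N biomarker statuses. Includes rigid
    mutual-information PET-to-anatomy registration with single-pass
    resampling, an iterative region-based partial-volume correction, a
    deterministic synthetic phantom generator for offline testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
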