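Package: sctqa
Title: Patient-Specific Quality Assurance of Synthetic CT for MR-Only
    Brain Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance (PSQA) of
    synthetic CT (sCT) images in an MR-only brain radiotherapy workflow.
    Provides geometry-aware volume handling with DICOM (CT series,
    RTDOSE, RTSTRUCT) and NIfTI readers, a deterministic ray-tracing
    dose engine with Siddon radiological path lengths, dose-volume
    histogram metrics (D2%, D95%, D98%, Dmean) and mean-error
    statistics, 3D local gamma analysis with an exhaustive brute-force
    oracle, tolerance-based failure classification with sensitivity,
    digitally reconstructed radiograph (DRR) generation with 2D/2D and
    3D rigid registration for patient-positioning comparison, and a
    synthetic head-phantom cohort generator with plantable sCT error
    modes for end-to-end testing of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
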