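Package: promrmc
Title: Multi-Reader Multi-Case Analysis for Prostate MRI CAD Reader Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing multi-reader, multi-case (MRMC)
    prostate MRI reader studies that compare conventional PI-RADSv2
    interpretation with computer-aided diagnosis (CAD) assisted reading.
    Implements the hybrid reader-case allocation (a common patient subset read
    by all readers plus pairwise reader blocks) with analytic and simulated
    power for the difference in average reader-specific sensitivity;
    sector-key matching of reader findings to ground-truth lesions with
    index-lesion designation; patient-level and lesion-level sensitivity and
    specificity at every PI-RADSv2 threshold with empirical ROC/AUC;
    disease-status-stratified bootstrap confidence intervals and Wald tests;
    the index of specific agreement between readers; mono-exponential
    apparent-diffusion-coefficient fitting with computed high-b-value signal
    synthesis; and a seed-reproducible synthetic-data generator emulating a
    two-session nine-reader study cohort so the full pipeline can be exercised
    without imaging or patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    RNifti,
    optparse
Config/testthat/edition: 3
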