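Package: agnorscreen
Title: AgNOR Quantification and Diagnostic Cut-Off Analysis for Oral Cytology Smears
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for argyrophilic nucleolar
    organizer region (AgNOR) counting in oral exfoliative cytology.
    Generates synthetic smear images and patient cohorts with known ground
    truth, counts NOR dots per nucleus from bounding-box annotations using
    classical image operators (per-crop Otsu thresholding and connected
    components with fused-dot merging), aggregates per-patient and
    per-group summaries, estimates diagnostic cut-off points on the ROC
    curve closest to perfect sensitivity and specificity, and quantifies
    human-versus-automated agreement with intraclass correlation
    coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
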