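Package: mammoseg
Title: Mammogram Preprocessing, Enhancement and Abnormal-Region Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for computerized mammogram analysis:
    pectoral-muscle removal by seeded region growing, morphological
    top-hat/bottom-hat contrast enhancement, and clustering-based
    segmentation of abnormal (mass) regions, together with the standard
    evaluation suite (MSE, PSNR, EME, confusion fractions, accuracy,
    sensitivity, specificity, Dice).  Includes a synthetic mammogram
    phantom generator with ground-truth breast, pectoral and lesion masks
    so the full pipeline can be exercised and validated without access to
    clinical images, readers and writers for the PGM and PNG formats used
    by public mammography archives, and a command-line interface for
    reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
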