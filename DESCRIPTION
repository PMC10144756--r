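Package: postiol
Title: No-History Intraocular Lens Power Formula Evaluation After Myopic
    Laser Refractive Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Back-calculates refractive prediction errors of no-history
    intraocular lens (IOL) power calculation methods in eyes with prior
    myopic laser refractive surgery, optimizes lens constants by zeroing
    the mean prediction error per IOL model, compares method accuracy
    across keratometry, axial-length and AL/K ranges with nonparametric
    paired tests, and applies a range-based multi-formula selection rule
    with an AL/K tie-break.  A synthetic-cohort generator with a
    ground-truth sidecar makes every pipeline stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
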