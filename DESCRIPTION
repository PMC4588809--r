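Package: predmet
Title: Predictive Metabolomics from GC-TOFMS Curve Resolution to
    Cross-Validated Pattern Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end predictive-metabolomics workflow for two-class
    comparisons of GC-TOFMS metabolite profiles.  Raw chromatographic cubes
    (samples x retention time x m/z) are resolved into pure elution profiles
    and mass spectra by windowed multivariate curve resolution (MCR-ALS with
    non-negativity and unimodality constraints), quantified by peak area,
    normalized against internal standards, and putatively identified by
    spectral-library matching with a retention-index gate.  The resulting
    feature tables are analyzed by OPLS-DA with w*-based variable selection,
    seven-fold cross-validation, CV-ANOVA significance testing, and ROC
    analysis of cross-validated score patterns with stratified bootstrap
    confidence intervals.  A synthetic-data module generates raw cubes and
    class-structured feature tables with known ground truth so that every
    stage of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
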