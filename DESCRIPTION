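Package: immunopolar
Title: Model-Based Inference of Immune Cell Polarization from Bulk Tumor
    Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers T-helper and macrophage polarization bias in homogenized
    tumor tissue from bulk gene expression using a Bayesian comparison of
    mutually exclusive gene-signature models scored on cohort z-scores.
    Provides the surrounding cohort workflow: median-ratio normalization,
    Ward clustering of immune gene panels, immune-infiltration scoring,
    principal component analysis with bootstrap noise thresholds and
    cross-study projection, Kaplan-Meier and Cox survival analysis with a
    random-signature hazard-ratio null ensemble, contingency and correlation
    statistics, optical-density color deconvolution of immunohistochemistry
    images, and a synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
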