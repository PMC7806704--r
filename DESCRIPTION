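Package: synermars
Title: Probiotic-Metabolite Synergy Inference with Multivariate Adaptive
    Regression Splines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits per-metabolite multivariate adaptive regression splines
    (MARS) models over combinatorial probiotic supplementation designs,
    prunes non-predictive terms by generalized cross-validation, and
    normalizes retained term coefficients to signed percentages of the
    prebiotic-alone reference level, yielding a metabolite-by-combination
    synergy matrix. Includes a synthetic-data generator with planted main,
    pairwise and tertiary synergies for end-to-end recovery testing, a
    2^-ddCt relative quantification utility for qPCR Ct tables, and CSV/TSV
    readers and writers with a thin command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
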