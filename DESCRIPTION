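Package: fraildex
Title: Deficit-Accumulation Frailty Index and Its Brain Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs deficit-accumulation frailty indexes from health-item
    tables with screening (rarity, missingness, collinearity) and
    completeness-gated scoring, and analyses their relationship to diagnostic
    group and brain measures: class-weighted gradient-boosted classification
    of diagnostic pairs with cross-validated AUC and additive (SHAP)
    attributions, mass-univariate ordinary-least-squares association of
    frailty with regional gray-matter volumes and ROI-to-ROI functional
    connectivity with false-discovery-rate control, subsampling-based
    between-group contrasts of association strength, image-quality
    (SNR/tSNR) covariates, and a synthetic cohort generator that emulates a
    three-group (cognitively unimpaired, Alzheimer's disease, frontotemporal
    lobar degeneration) clinical study design so that every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    kernlab,
    lhs,
    multcomp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
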