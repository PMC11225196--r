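Package: sevindex
Title: Disease Severity Index from Brain Atrophy Patterns via OPLS-DA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and evaluates a continuous "disease severity index" for
    structural-MRI morphometry. Regional cortical thickness and subcortical
    volume panels are preprocessed (head-size residualization, normative age
    detrending, unit-variance scaling), an orthogonal projections to latent
    structures discriminant model (OPLS-DA, NIPALS) is trained to separate
    cognitively normal individuals from amnestic MCI or dementia patients,
    and projected subjects are classified as CN-like or disease-like at a
    smoothed-CDF maximum-separation cutoff, with optional pruning of
    minimal-atrophy training cases. Includes a synthetic memory-clinic cohort
    generator with longitudinal progression, 10-fold cross-validated R2/Q2,
    permutation testing, and longitudinal evaluation of classifications
    (sensitivity/specificity, ROC with DeLong comparison, Kaplan-Meier,
    log-rank and Cox proportional-hazards models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
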