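Package: idiodyn
Title: Idiographic Analysis of Intensive Longitudinal Daily-Diary Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Person-specific (N = 1) analysis of intensive longitudinal
    daily-diary data. Provides intraindividual descriptive statistics
    (iM, iSD, variability classification), hormone-phase-moderated
    residualized regression with simple-slopes decomposition, and
    person-specific hybrid unified structural equation model (uSEM)
    temporal networks estimated by maximum likelihood with Lagrange
    multiplier forward search over contemporaneous paths, lagged paths
    and residual covariances. Includes a synthetic daily-diary generator
    with known structural ground truth (phase regimens, structural VAR
    dynamics, phase-moderated outcomes, Likert discretization and
    diary-compliance missingness) so every analysis stage is testable
    without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'diary-data.R'
    'synthetic-diary.R'
    'descriptives.R'
    'moderated-regression.R'
    'usem-fit.R'
    'usem-search.R'
    'pipeline.R'
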