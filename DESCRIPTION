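Package: qsarGFA
Title: Genetic Function Approximation QSAR Modelling with Friedman
    Lack-of-Fit Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR)
    regression models by genetic function approximation (GFA): a genetic
    algorithm evolves a population of linear equations (molecular-descriptor
    subsets) scored by the Friedman lack-of-fit statistic, with ordinary
    least-squares or genetic partial least-squares (G/PLS) fitting of each
    candidate.  Provides the full statistic suite used to judge such models
    (R-squared, adjusted R-squared, F, Friedman LOF, leave-one-out
    cross-validated q-squared, standardized coefficients and descriptor
    importance ranking), a block-correlated synthetic descriptor generator
    with known ground truth for benchmarking subset selection, and a packaged
    descriptor/activity dataset of 59 benzodiazepine-2,5-dione HDM2
    antagonists with two published descriptor panels, from which the
    corresponding published models are reproduced end to end, including
    predictions for newly designed compounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'DescriptorTable.R'
    'units.R'
    'ols.R'
    'statistics.R'
    'pls.R'
    'gfa.R'
    'synthetic.R'
    'reporting.R'
    'hdm2.R'
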