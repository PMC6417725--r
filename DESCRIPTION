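Package: qsarcocktail
Title: Cocktail Ensemble QSAR Classifiers for Highly Imbalanced Bioassay Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary quantitative structure-activity relationship (QSAR)
    classifiers from large, highly imbalanced high-throughput screening
    datasets. Provides SMILES structure curation with counterscreen-aware
    activity labelling, substructure-key and descriptor featurization with
    Yates chi-squared preselection, partial-logistic-regression cocktail
    ensembles, a two-component applicability domain (structural similarity
    plus class-probability refinement), iterative rational selection of
    training-set inactives, Cooper-statistic validation with
    prevalence-adjusted predictive values, Y-randomization, and structural
    alert ranking. A seeded synthetic chemistry generator with planted
    activity alerts makes the whole workflow testable without external data.
    Requires the OpenBabel command-line tool for chemistry primitives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mixOmics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    caret,
    withr
SystemRequirements: OpenBabel (>= 3.0) command-line tool 'obabel' on PATH
Config/testthat/edition: 3
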