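Package: TcellOpt
Title: Dose-Response Design, Desirability Optimization, Limiting-Dilution
    Frequency Estimation and Notch Activity Scoring for Engineered T Cell
    Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for optimizing cytokine environments in
    pluripotent stem cell derived T cell differentiation. Constructs
    orthogonal central composite designs with logarithmic concentration
    scaling, fits polynomial dose-response surfaces to phenotype cell
    counts by least squares (with optional greedy third-order term
    selection), converts fitted surfaces into Derringer-style desirability
    functions combined by geometric mean, and locates optimal cytokine
    concentrations by a basin-hopping global search constrained to the
    design hypersphere. Also estimates progenitor frequencies from
    limiting-dilution assays under the single-hit Poisson model, applies
    single-cell RNA-seq quality-control filters and library-size
    normalization, and computes a bin-matched-control notch activity score
    with condition comparison. Ships seed-deterministic synthetic data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
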