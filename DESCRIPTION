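Package: pcflux
Title: Protein-Constrained Metabolic Modelling with Transcriptome Overlay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds protein-constrained genome-scale metabolic models
    (PC-models) by augmenting a stoichiometric model with protein, enzyme
    complex and catalytic-capacity variables under a proteome mass budget.
    Transcriptome samples are overlaid onto the PC-model by convex quadratic
    programming to obtain context-specific models; effective catalytic rate
    constants are calibrated across sample groups by a bilinear program; the
    contextualised models support protein-constrained flux balance and flux
    variability analysis, Spearman-based classification of reactions by
    expression dependence, transcriptome-consistency diagnostics, and linear
    programming identification of minimal protein-overexpression
    (debottlenecking) strategies. Includes readers and writers for SBML
    Level 3 FBC and COBRA-JSON models, protein FASTA and transcript tables,
    and a seeded synthetic-fixture generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    quadprog,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
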