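Package: fluxcord
Title: Classifying Metabolic Flux Regulation by Concordance of
    Transcriptomics, Metabolomics and Sampled Fluxes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates transcriptomics and metabolomics with a
    constraint-based metabolic model to classify each reaction's flux
    variation across sample groups as transcriptionally regulated,
    metabolically regulated, both, or other. Expression data are reduced
    to Reaction Activity Scores (RAS) through gene-protein-reaction
    rules, metabolite abundances to mass-action Reaction Propensity
    Scores (RPS), and per-group flux distributions are obtained by
    near-uniform sampling of the constrained flux polytope after
    building cell-relative models (medium, exchange-ratio and
    growth-yield constraints, RAS-scaled flux variability bounds).
    Pairwise variation signs of the three datasets are compared with
    Cohen's kappa against an empirical resampling null with
    Benjamini-Hochberg FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    boot,
    xml2,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metabolomics, Transcriptomics, Network, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'concordance.R'
    'constraints.R'
    'fixtures.R'
    'gpr.R'
    'lp.R'
    'model.R'
    'pipeline.R'
    'ras.R'
    'rps.R'
    'sampler.R'
    'sbml.R'
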