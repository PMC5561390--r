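Package: SeroRepertoire
Title: Autoantibody Repertoire Analysis for Protein Microarray Serology
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for serum screens on planar protein
    microarrays of the ProtoArray type. Reads GenePix-style scan tables,
    normalizes per-array technical effects with a robust linear model
    fitted on control-probe series, detects and removes print-contamination
    artifacts, standardizes signals against a healthy-control cohort and
    calls autoantigens (z-score exceeding a threshold in a minimum number
    of patients), and relates the called repertoire to clinical phenotype:
    empirical-Bayes moderated t-tests per manifestation, antigen
    correlations, per-sample variance contrasts, PCA, hierarchical
    clustering, manifestation-count regression, Nemenyi mutation-group
    comparisons, longitudinal pair overlaps, hypergeometric annotation
    enrichment and resampling nulls for continuous gene properties. A
    synthetic-data module generates ground-truth-labelled scans, metadata
    and annotations so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, Microarray, Normalization, ImmunoOncology
RoxygenNote: 7.3.3
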