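Package: gliatrace
Title: Fibre-Photometry Signal Processing and Brain-Wide Astrocyte
    Ensemble Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for studies of behaviourally relevant
    astrocyte ensembles. Implements the fibre-photometry chain
    (time-division demultiplexing, moving-average smoothing, linear
    bleaching correction, isosbestic ratio dF/F, transient peak/AUC/
    half-decay metrics, zero-phase band-pass filtering and
    threshold-based calcium event detection), brain-wide Fos-ensemble
    density screening across a region ontology (Levene-routed
    ANOVA/Tukey or Kruskal-Wallis/Dunn tests with Benjamini-Hochberg
    false-discovery control and fold changes), and single-cell in situ
    hybridization statistics (marker normalization, within-sample
    z-scoring, high-expression classification, co-expression indices,
    gene-gene correlation and rank tests). A synthetic-data module
    generates photometry streams, negative-binomial region count tables
    and log-normal cell intensity tables with known ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
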