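Package: selexkmer
Title: Linear k-mer Models of Transcription Factor Specificity from HT-SELEX Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains linear k-mer binding models from high-throughput SELEX read
    sets by solving the binary-presence design system Ax = b, where rows are
    reads, columns are canonical k-mers and b labels enriched versus random
    reads. Provides three k-mer feature-selection strategies (most frequent,
    most enriched by count difference or fold change, and greedy backward
    elimination driven by 10-fold cross-validation), threshold classification
    with normal-approximation confidence intervals, Mann-Whitney AUC evaluation
    of ChIP-seq-style peak sequences, position weight matrix ingestion and
    max-log-odds scanning for head-to-head comparisons, and a SELEX
    enrichment-cycle simulator that supplies ground-truth data for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
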