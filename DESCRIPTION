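Package: miningabs
Title: Mining Associated Biomarkers Across Microarray Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Cross-platform meta-analysis of gene-expression datasets that
    mines small panels of associated biomarkers for tumor/normal
    classification.  Platforms with different probe content are bridged by
    a probe-sequence similarity matrix (one minus the pairwise
    maximum-likelihood evolutionary distance under the Jukes-Cantor
    model), candidate gene panels are scored by a common logit model (the
    average log-likelihood of per-dataset sibling logistic fits), and the
    panel space is searched with an elitist genetic algorithm.  Includes
    readers and writers for probe FASTA/annotation, expression and
    similarity-matrix tables, a reciprocal leave-one-out evaluation
    protocol with a leave-one-biomarker-out ablation, and a synthetic
    multi-platform data generator with planted logistic signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
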