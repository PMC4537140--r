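Package: palmeta
Title: Curation and Meta-Analysis of Palmitoylation Proteomics Compendia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Consolidates heterogeneous per-study palmitoyl-protein identifier
    lists into a gene-level compendium with reviewed-entry priority and
    cross-species homolog unification, clusters study presence/absence
    profiles with binary distance, average linkage and multiscale bootstrap
    support, tests annotation terms for over-representation against a custom
    mass-spectrometry proteome background with fold-enrichment and false
    discovery rate thresholds, quantifies overlap with a synaptic gene list
    by exact tests, and classifies disease-causing mutations at known or
    putatively palmitoylated cysteines. A synthetic-data generator with
    planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
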