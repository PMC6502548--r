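Package: cexscreen
Title: Candidate Prioritisation for the Aspergillus niger Citrate Exporter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested re-implementation of the in-silico screen that pinpointed
    the Aspergillus niger citrate exporter CexA. Three candidate-generation
    tracks (profile-HMM scan of the proteome against seed alignments of
    characterised citrate transporters, a producer/non-producer homology
    asymmetry screen over five comparator species, and genomic proximity to the
    citrate synthase gene citA) are funnelled through an ordered expression
    filter cascade (average nucleotide coverage and per-contrast log2
    fold-change with Benjamini-Hochberg FDR) and ranked by the designated
    production contrast. A synthetic-data generator plants a ground-truth
    exporter with the full evidence signature so that every stage, and the
    end-to-end recovery of the planted gene, is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
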