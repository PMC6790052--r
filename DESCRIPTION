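Package: cisgrammar
Title: Sliding-Window Enhancer Prediction and Binding-Site Grammar Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-species analysis of compact cis-regulatory
    elements (enhancers) in small genomes. Scores candidate regions against a
    characterized reference enhancer by sliding a fixed-width window and
    combining four structural features (shared oligomers, oligomer ordering,
    relative genomic position, and conserved transcription-factor binding
    motifs), scans degenerate IUPAC binding motifs on both strands, quantifies
    conservation of enhancer grammar (motif number, order, orientation,
    spacing, and helical phase), performs in-silico binding-site mutagenesis
    (knockout and displacement), and generates seeded synthetic loci with
    planted ground-truth enhancers for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
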