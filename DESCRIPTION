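Package: utrmotif
Title: Discovery and Characterization of Conserved 3' UTR Decay Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for discovering candidate cis-regulatory elements in
    mammalian 3' UTRs and characterizing their regulatory impact. Enumerates
    8-mers in multi-species 3' UTR alignments, counts cross-species conserved
    instances against composition- and abundance-matched shuffled-control
    backgrounds, scans degenerate (IUPAC) motifs such as UAASUUAU with
    co-occurrence and positional analyses, and tests motif-bearing
    transcripts for enrichment in differential-expression data using exact
    hypergeometric and one-sided Kolmogorov-Smirnov statistics. Includes a
    synthetic-data generator that plants motifs with known cross-species
    retention and expression effects so every stage is testable without
    external genome annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
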