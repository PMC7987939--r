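Package: sbsites
Title: Transposon Integration Site Calling and Target Dinucleotide
    Consensus Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls Sleeping Beauty transposon integration sites from
    junction (LM-PCR) sequencing reads, classifies TA versus non-TA
    target dinucleotides, tabulates per-library dinucleotide counts and
    non-TA proportions, and builds strand-aware flanking-sequence
    position frequency matrices and information-content consensus
    profiles that expose the junction-side asymmetry of non-TA target
    consensus and its correspondence to the transposon end sequence.
    Includes a deterministic synthetic-data generator (reference
    genome, ground-truth integration events, junction FASTQ reads) so
    the full pipeline is testable without external data, an internal
    seed-and-extend read aligner for desk-scale genomes, and SAM import
    so an external aligner can substitute.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
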