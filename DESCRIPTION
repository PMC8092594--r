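Package: peakTargets
Title: Replicate-Consensus ChIP-seq Peak Filtering and Target-Gene Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies candidate transcription-factor target genes from
    replicate ChIP-seq peak calls. Consensus binding regions are defined as
    genomic intervals supported by a significant (FDR-filtered) peak in every
    treatment replicate and in no control replicate; regions are assigned to
    genes falling within a configurable promoter/downstream window subject to
    an intervening-gene veto; positional enrichment of binding in promoter,
    transcribed and downstream zones is tested against a bootstrap null of
    randomly placed sites; and overlap between target-gene sets is tested
    with a two-tailed Fisher's exact test. A seeded synthetic-data generator
    produces genomes, replicate peak calls and reference gene sets with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
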