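Package: srnadigger
Title: Bidirectional Mining of Plant Small RNA-Target Pairs from
    Degradome and Small RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies plant small RNA (sRNA) target genes bidirectionally
    from transcript (cDNA) sequences, abundance-collapsed sRNA
    high-throughput sequencing reads, and degradome (PARE) 5'-end reads.
    Forward mining scores sRNA/transcript duplexes with a position-dependent
    complementarity penalty, validates candidate binding sites against
    degradome cleavage signal concentrated at the slicer position opposite
    sRNA position 10, and cross-checks each pair by reverse mining; reverse
    mining recovers, for any cleavage site, every expressed sRNA whose
    duplex with a 30-nt bait around the site would direct cleavage there,
    including unannotated co-regulators. Ships a deterministic synthetic
    data generator with planted interactions for end-to-end validation, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
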