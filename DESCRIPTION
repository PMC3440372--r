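Package: sprfinder
Title: Discovery of Novel Small Noncoding RNAs from Small RNA-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the computational discovery of novel
    small noncoding RNAs (sncRNAs) from deep-sequenced small-RNA libraries.
    Reads are classified against known RNA classes by exact substring
    matching with a fixed class hierarchy, 20-23 nt reads that are neither
    miRNA nor rRNA are screened for unique genomic loci, proximal regions
    are folded with a base-pair-maximization (Nussinov) folder, and
    candidates are kept when the read lies within one arm of a hairpin
    stem. Includes reads-per-million normalization, cross-library
    enrichment ratios, 3-prime non-templated variant calling, in-silico
    poly(A)-tailed RT-PCR amplicon sizing, and a synthetic-data generator
    that plants hairpin-borne sncRNAs inside a piRNA cluster so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
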