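Package: iCLIPkit
Title: iCLIP Crosslink-Site Analysis, Peak Calling, Motif Scoring and
    Splice-Switching Oligonucleotide Target Design
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for individual-nucleotide resolution
    crosslinking and immunoprecipitation (iCLIP) data: demultiplexing of
    reads carrying an RRRIIIIRR barcode with a 5-bp random tag, adapter and
    quality trimming, mismatch-tolerant PCR-duplicate collapsing,
    single-nucleotide crosslink-site assignment from read truncations and
    crosslink-induced deletions, permutation-based binding-peak detection
    with superlocal background windows and Benjamini-Hochberg FDR control,
    k-mer motif enrichment with log2 position scoring matrices, genomic
    distribution and metagene profiling of binding, cassette-exon
    percent-spliced-in quantification from junction counts, and selection of
    splice-switching oligonucleotide target sites downstream of 5' splice
    sites. A fully seeded synthetic-data generator with known ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    GenomeInfoDb,
    igraph
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Sequencing, Transcriptomics, AlternativeSplicing, PeakDetection,
    MotifDiscovery
RoxygenNote: 7.3.3
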