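Package: kinfamscan
Title: Genome-Wide Kinase Gene-Family Survey Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide surveys of plant MAP kinase
    kinase kinase (MAPKKK) gene families: query-based homology screening with
    an identity threshold, redundancy removal, PROSITE-style kinase hallmark
    validation, ZIK/MEKK/Raf subfamily classification by conserved signature
    motifs, theoretical isoelectric point (Bjellqvist pK set) and average
    molecular weight, progressive multiple alignment with neighbor-joining
    phylogeny and bootstrap support, cDNA-to-genome exon/intron inference,
    tandem and dispersed duplication calling, and RPKM expression
    quantification from uniquely mapped reads. Includes a synthetic
    cotton-like dataset generator with a full truth table so every stage can
    be scored for exact parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
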