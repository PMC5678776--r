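Package: plastidmarkers
Title: Chloroplast Marker Development from Plastome Alignments and RAD-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two complementary strategies for developing polymorphic
    chloroplast DNA markers. The first scans a multi-plastome alignment for
    conserved islands (runs of identical columns) and the variable "seas"
    between them, scores every region by potentially informative characters
    (SNPs plus indel events) at intrageneric and intergeneric levels, and
    ranks candidate regions for Sanger-scale marker design. The second
    sub-assembles chloroplast fragments directly from paired-end RAD-Seq
    reads anchored at restriction sites (tag clustering, overlap-layout
    sub-assembly, paired/overlap tags, reference-ordered scaffold), and
    computes population-genetic statistics (nucleotide diversity, Watterson
    theta, Hudson FST) on the conserved loci recovered across individuals.
    A seed-deterministic simulator of circular references, mutated
    individuals and in-silico restriction-digest paired-end reads supports
    end-to-end validation against planted truth sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
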