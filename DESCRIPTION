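Package: apakit
Title: Alternative Polyadenylation Analysis from 3'-End Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing alternative cleavage and polyadenylation
    (APA) from 3'-end sequencing data. Identifies poly(A)-site-supporting
    reads by their untemplated adenosine tails, clusters cleavage positions
    into poly(A) sites (PAS), filters internal-priming artifacts, classifies
    PASs by upstream A[A/U]UAAA hexamer and gene region, and tests per-gene
    3'UTR shortening/lengthening and intronic PAS activation/repression using
    relative-expression statistics (RE/RED) with exact tests. Includes
    gene-level differential expression from CDS-restricted counts, coupling
    analyses between APA and expression, functional-consequence annotation
    (miRNA target sites removed by 3'UTR shortening, protein domains removed
    by intronic APA), and a fully seeded synthetic-data generator producing a
    toy genome, annotation, ground-truth APA program, count matrices and
    simulated 3'-end reads for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
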