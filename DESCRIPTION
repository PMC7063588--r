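Package: wheatGMS
Title: Candidate Triage, Polyploid CRISPR Guide Design and Edit Genotyping
    for Genic Male Sterility in Hexaploid Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico workflow for identifying and knocking out
    male-fertility genes in allohexaploid wheat. Provides count-based
    differential-expression triage of stamen/pistil libraries with
    homoeologue-set significance codes, a subgenome-resolved gene-family
    census by Pfam domain with a neighbor-joining phylogeny, Cas9 guide
    selection that requires conservation across all three homoeologues with
    restriction-site screenability at the cut site, amplicon-based indel
    genotyping with coding-consequence prediction over six alleles, and a
    genotype-to-fertility caller implementing the rule that a single
    functional allele at any homoeologue maintains male fertility. A
    synthetic hexaploid data generator supplies ground-truth fixtures for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
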