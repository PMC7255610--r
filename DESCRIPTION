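Package: srnaAnnot
Title: Multi-Mapping Aware Annotation and Quantification of Small RNA Classes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies small-RNA annotation classes from mapped sRNA-seq reads
    while exploiting all hits of multi-mapping reads. Reads whose hits agree on a
    single annotation class are rescued; irreducible ambiguity is reported
    explicitly as merged annotations formed by concatenating the equally ranked
    classes. Annotation classes, strand-orientation requirements and a priority
    ordering are taken from a plain-text configuration file, and missing features
    (introns, 5'/3' UTRs, upstream and downstream regions) are inferred on the fly
    from an Ensembl-style GTF. Alignments are read from SAM/BAM with multi-mapping
    encoded either as one record per hit with an NH tag or as BWA-style XA tags,
    and a companion tool adds NH tags to bowtie output. Four counting strategies
    (default, unique, random, ratio) are provided, together with class-level and
    feature-level count tables and per-read annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
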