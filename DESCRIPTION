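Package: divbench
Title: Divergence-Controlled Read Simulation and Mapper/Caller Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for benchmarking short-read mappers and variant callers
    in highly divergent genomic regions such as the human HLA locus.
    Simulates exome-like paired-end reads from target regions mutated to a
    controlled divergence level (the ratio of permuted SNPs and INDELs over
    total bases), tracks the reference origin of every read and variant, and
    scores any mapper's SAM/BAM or caller's VCF against the recorded truth:
    soft-clip-adjusted mapping accuracy with distance binning, SNP and INDEL
    sensitivity and precision, overall genotype concordance, known/novel
    classification against a catalog, SnpCluster/LCR/SD context annotation,
    and HLA-region stratification. External mappers and callers are never
    run; the package produces their inputs and grades their outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
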