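Package: emsnv
Title: Expectation-Maximization Ensemble SNV Calling with Decision-Tree
    Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-step single-nucleotide variant (SNV) caller for diploid
    genomes. Aligned reads are stratified into base-quality "learners" and an
    unsupervised Dawid-Skene-style expectation-maximization algorithm
    estimates per-learner confusion matrices, reference-conditional genotype
    priors, and per-locus posteriors over the ten diploid genotypes; loci
    whose decided genotype differs from the homozygous reference become SNV
    candidates. A shallow (depth <= 5) decision tree trained on genotype,
    depth, alternate-allele fraction, and posterior entropy then removes
    untrue candidates. Includes a VCF 4.2 writer, a genotype-aware
    precision/recall/F1 evaluator against a truth VCF within optional
    confident regions, and a seeded read/variant simulator that provides a
    fully synthetic test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    jsonlite,
    rpart,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
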