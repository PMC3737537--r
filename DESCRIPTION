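Package: smrnaclass
Title: Classification of Small RNA-Seq Loci into Non-Coding RNA Functional Classes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies transcribed small-RNA loci from aligned short reads and
    classifies them into non-coding RNA functional classes (lincRNA, miRNA,
    scRNA, C/D box snoRNA, snRNA, transposon-derived RNA) using interpretable
    features of the read pileup: the 14-30 nt read-length spectrum as log-odds,
    antisense read abundance, 5' and 3' cleavage positional entropy, read base
    composition and a folding stability score of the locus with flanking
    sequence. Provides backwards feature elimination over random forests with a
    one-standard-error rule, stratified (optionally nested) cross-validation,
    permutation-baseline accuracy, stability selection with per-class feature
    direction reports, random-forest proximity multidimensional scaling,
    cross-dataset validation, and a synthetic class-specific read-pileup
    generator so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    methods,
    tools,
    randomForest,
    Rcpp,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
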