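Package: cernet
Title: Genome-Wide ceRNA Network Inference from Bulk Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers genome-wide competing endogenous RNA (ceRNA) networks
    between long noncoding RNAs and coding genes from bulk tissue
    transcriptomes, and prioritizes candidate regulator lncRNAs. Provides
    expression normalization with immune-infiltration covariate adjustment,
    linear-model differential expression, genomic clustering of
    differentially expressed genes with a permutation null, blockwise
    genome-wide expression correlation with Bonferroni control, shared
    miRNA-binding-site filtering, preranked gene set enrichment screens,
    single-sample pathway activity scoring, overexpression-experiment
    comparisons, and a fully seeded synthetic cohort generator with planted
    ground truth so that every stage of the pipeline can be validated
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
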