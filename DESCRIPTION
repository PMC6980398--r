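Package: ageomics
Title: Multi-Omic Analysis of Age by Genotype Brain Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 2x2 (age by genotype) bulk brain
    transcriptome and proteome studies. Provides CPM filtering, TMM
    normalisation, removal of unwanted variation from replicate groups,
    empirical-Bayes moderated differential expression for the four pairwise
    contrasts, classification of multi-contrast expression patterns
    (inversion, accelerated aging, failure to regulate), rotation gene-set
    testing, signed weighted co-expression networks with topological overlap
    and a dynamic-hybrid tree cut, permutation-based cross-network module
    preservation (Z-summary), promoter motif scanning with hypergeometric
    over-representation, peptide-to-protein proteomics processing with
    left-censored imputation and median polish, and a synthetic-study
    generator that plants all of the statistical structure the pipeline
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    limma,
    edgeR,
    survival,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
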