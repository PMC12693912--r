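Package: mqtlkit
Title: Meta-QTL Analysis and Candidate-Gene Screening for Complex Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for condensing published quantitative trait loci (QTLs)
    into consensus meta-QTLs and funnelling the genes they contain down to
    high-confidence candidates. Standardizes QTL confidence intervals with
    population-specific formulas, merges per-study genetic maps into a
    consensus map, projects QTLs onto it, and clusters them chromosome-wise
    with a heteroscedastic Gaussian mixture model whose component count is
    chosen by majority vote over five information criteria (AIC, AICc, AIC3,
    BIC, AWE). Meta-QTLs are validated against GWAS marker-trait
    associations in physical windows, and resident genes are screened
    through differential-expression, fuzzy c-means temporal-clustering and
    promoter cis-element filters. A synthetic-data generator emulates
    multi-study QTL panels, SNP association panels, genomes and two-genotype
    expression time courses so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
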