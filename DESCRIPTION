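Package: ftqtl
Title: Flowering-Time Association Mapping, QTL Calling and Selection Scans
    in Structured Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end association-and-adaptation analysis for
    multi-environment flowering-time trials in inbred crop panels such as
    rapeseed (Brassica napus). Provides multi-environment phenotype
    statistics, two-way fixed-effects ANOVA and broad-sense heritability
    from expected mean squares; six population-structure-aware
    marker-trait association models (naive, Q, PCA, K, Q+K, PCA+K) with
    an EMMAX-style mixed linear model; pooled Benjamini-Hochberg FDR
    thresholding; merging of significant SNPs into named QTL intervals;
    a Weir-Cockerham F_ST sliding-window selection scan between
    growth-habit sub-populations; interval overlap of QTLs and candidate
    genes with selection regions; and a Balding-Nichols synthetic-cohort
    generator with a truth file so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
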