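Package: svexpr
Title: Integrative Analysis of Somatic Structural Variants, Gene Expression,
    Enhancer Translocation and DNA Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Relates somatic structural-variant (SV) breakpoints near genes
    to altered gene expression in tumor cohorts. Annotates breakpoints to
    strand-aware gene-relative windows (gene body, 0-20/20-50/50-100 kb
    upstream, 0-20 kb downstream), builds a binary SV event matrix, fits
    nested linear models of log expression on SV status with cancer-type and
    copy-number covariates, estimates false discovery rates by the
    Storey-Tibshirani method, and calibrates significance by permutation of
    sample labels. Quantifies enhancer hijacking through counts of enhancer
    elements juxtaposed within 0.5 Mb of rearrangement breakpoints and
    changes in nearest-enhancer distance, and integrates DNA methylation via
    logit-transformed beta values and Pearson correlations. Includes a
    synthetic-cohort generator with known ground truth so the whole pipeline
    is testable without consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
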