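Package: methylex
Title: Methylome Summarization and Polynomial Modeling of Gene Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Summarizes whole-genome bisulfite per-cytosine methylation
    calls into CG/CHG/CHH levels over genome windows, gene regions
    (up-stream 1 kb, gene body, first 500 bp, down-stream 1 kb),
    transposable elements and TSS-anchored metaprofiles; fits Z-standardized
    degree-3 polynomial models of log gene expression with forward BIC
    stepwise selection and k-fold cross-validation; interrogates fitted
    response surfaces (conditional cubic profiles, stationary and inflection
    points); tests GO-term enrichment in highly methylated genes; and
    generates fully synthetic input bundles (genome, gene models, repeats,
    cytosine counts, expression, annotations) with configurable region
    methylation levels, inter-context correlations and expression signal.
License: MIT
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
    Biostrings,
    rtracklayer,
    MASS,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
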