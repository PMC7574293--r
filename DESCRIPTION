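Package: sputodeconv
Title: Cell-Type Deconvolution and RNA-Degradation Correction for Sputum Omics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for mixed-cell induced-sputum omics. Provides
    regression-based deconvolution of cell type-specific expression and
    methylation profiles from differential cell counts, solved per feature as a
    box-constrained least-squares problem (quadratic program) so that
    methylation estimates stay within [0,1] and expression estimates within the
    dynamic range of the array; standard-error estimation and Welch tests on
    the deconvolved estimates; in-silico correction of RNA-degradation (RIN)
    bias by correlation filtering or per-probe linear regression with PCA
    diagnostics; expression/methylation array preprocessing (background
    correction, quantile normalization, flag- and annotation-based probe
    filtering); differential expression and methylation calling with
    Benjamini-Hochberg adjustment; merging of differentially methylated
    positions into regions, promoter/gene-body mapping and hypergeometric
    gene-set overrepresentation; and a synthetic sputum-study generator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, DNAMethylation, MethylationArray, Microarray,
    Preprocessing, Normalization, DifferentialExpression,
    DifferentialMethylation, Regression
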