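Package: glycoNTC
Title: Glycolysis and Proliferation Analysis for Neural Tube Closure
    Single-Cell and Metabolomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis toolkit linking glycolytic gene expression
    to proliferation in the closing neural tube. Provides UMI- and
    mitochondrial-based quality control and log normalization of single-cell
    count matrices, rank-based two-group differential expression, per-population
    metabolic pathway scoring with minimum-population normalization and
    stage/genotype fold-change aggregation, threshold co-expression statistics
    for cell-cycle gene pairs, intersection of predicted miRNA-target lists with
    pathway gene sets, pooled-QC drift normalization and differential abundance
    for untargeted LC/MS metabolomics, and linear-region slope estimation for
    coupled phosphofructokinase absorbance assays. Ships negative-binomial and
    log-normal simulators with serialized ground truth so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
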