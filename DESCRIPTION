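Package: CtStability
Title: Reference-Gene Stability Evaluation and Relative Quantification
    for RT-qPCR Ct Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates candidate reference (housekeeping) genes for
    RT-qPCR normalisation from threshold-cycle (Ct) tables with sample
    metadata. Implements the GeNorm M value with stepwise exclusion and
    the pairwise-variation (V_n/n+1) criterion for the optimal number of
    reference genes, the NormFinder inter-/intra-group variance
    decomposition and stability value, the BestKeeper index with
    correlation and dispersion statistics, the comparative delta-Ct
    method, summed final-rank and RefFinder-style geometric-mean rank
    aggregation, and delta-delta-Ct relative quantification of target
    genes with nonparametric group testing. Includes a seeded synthetic
    Ct-data generator emulating multi-group trauma study designs so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, qPCR, Normalization, Preprocessing
RoxygenNote: 7.3.3
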