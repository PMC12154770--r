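Package: gardensort
Title: Pool-Seq Analysis of Replicated Multi-Garden Evolution Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evolve-and-resequence experiments in which a fixed
    panel of inbred founder accessions of a selfing annual plant is sown in
    replicated outdoor gardens across contrasting climates and tracked by
    pooled whole-genome sequencing. Provides a forward simulator of
    accession sorting under Gaussian stabilizing selection with selfing,
    optional outcrossing and pool-seq observation; reconstruction of allele
    and founder-accession frequencies from pooled counts with linkage-based
    error reduction; Wright-Fisher and accession-sorting neutral nulls with
    excess-variance tests; Hudson F_ST, PCA of frequency change,
    repeatability and heritability of frequency change; LD-block
    partitioning with a replicate-consistent likelihood-ratio selection
    scan and block-overlap permutation tests; per-accession stabilizing
    selection fits with realized climatic optima and adaptation lags;
    experimental genome-environment association with weighted-Z block
    pooling and FDR control; and forecasting via logistic allele
    trajectories, selection coefficients, genomic offset with leave-one-out
    validation, survival models and census rescue fits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
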