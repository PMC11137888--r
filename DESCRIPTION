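Package: rgstab
Title: Reference Gene Stability Analysis for RT-qPCR Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening and validation of candidate reference genes for
    RT-qPCR normalization. Implements transcriptome-based candidate screening
    by coefficient of variation of FPKM, four expression-stability
    algorithms (comparative Delta Ct, BestKeeper descriptive statistics,
    geNorm M-values with pairwise-variation analysis of normalization
    factors, and the NormFinder model-based variance decomposition),
    RefFinder-style comprehensive ranking by geometric mean of ranks,
    standard-curve amplification-efficiency fitting, and multi-reference-gene
    2^-ddCt relative quantification. Includes a synthetic qPCR data
    generator with known ground truth for benchmarking every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
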