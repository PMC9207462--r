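Package: refstab
Title: Reference Gene Selection and Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying and validating reference (housekeeping)
    genes for RT-qPCR normalization. Screens candidates from RNA-seq FPKM
    matrices by mean expression, maximum fold change and coefficient of
    variation; ranks candidate stability from Cq data with four algorithms
    (comparative delta-Ct, BestKeeper, geNorm and NormFinder); aggregates the
    four rankings into a consensus by the geometric mean of ranks; estimates
    amplification efficiency from 10-fold dilution standard curves; and
    quantifies target-gene expression by the 2^-ddCq method with one or two
    reference genes. A synthetic-data module generates FPKM matrices, Cq
    experiments, dilution series and target-gene datasets with recorded ground
    truth so every stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
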