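Package: refstab
Title: Discovery and Validation of Reference Genes for Expression
    Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: A pipeline for discovering and validating reference
    (housekeeping) genes for quantitative expression studies. Candidate
    genes are screened from RNA-seq count matrices with a three-stage
    stability filter cascade (fold-change window between genotype groups,
    expression window, and dispersion relative to a reference library).
    Candidates are then validated from qPCR quantification-cycle (Cq)
    data: technical replicates are collapsed with an outlier-discard
    rule, amplification efficiencies are estimated from serial-dilution
    standard curves, and gene stability is ranked with four established
    algorithms (comparative delta-Ct, BestKeeper, NormFinder and geNorm)
    combined into a comprehensive geometric-mean rank. Target genes can
    be normalized against single- or multi-reference schemes, and a
    synthetic-data module simulates count matrices and qPCR experiments
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
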