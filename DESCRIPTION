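Package: bsascan
Title: Bulked-Segregant QTL-seq Analysis with SNP-Index Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QTL-seq bulked-segregant analysis (BSA-seq) of
    biparental populations: per-bulk SNP index and delta(SNP index)
    statistics with depth and low-index filtering, sliding-window genome
    scans, Monte-Carlo null confidence intervals and empirical p-values,
    QTL-region calling, and downstream single-marker association
    statistics (LOD, phenotypic variance explained, additive effect).
    Includes a full F2 bulked-segregant simulator (Haldane meiosis,
    additive-plus-dominance trait model, extreme-tail bulk selection,
    binomial read sampling) for power studies and pipeline validation,
    plus readers and writers for allele-depth VCF, TSV and BED.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
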