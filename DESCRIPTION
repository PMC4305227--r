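Package: pbmcopd
Title: Dynamic Gene-Expression Biomarker Discovery in COPD and Its Acute
    Exacerbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for discovering disease-specific and
    exacerbation-specific dynamic gene-expression biomarkers in peripheral
    blood mononuclear cells (PBMCs) from a five-group case-control design
    (healthy controls, stable COPD, and acute exacerbation sampled at
    hospital days 1, 3 and 10). Implements RMA-style preprocessing (quantile
    normalization, log2 transform, median-polish probe summarization),
    fold-change differential calling over the ten group comparisons,
    co-differential biomarker panel selection, two-step trajectory pattern
    classification, the Digital Evaluation Score System (DESS) composite
    clinical severity score with severity-concordance checks, hypergeometric
    gene-set over-representation, and a seeded synthetic-study generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
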