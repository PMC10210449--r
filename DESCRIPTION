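Package: scSexBias
Title: Decomposition of Sex-Biased Gene Expression into Abundance and
    Regulatory Components
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to separate sex differences in tissue-level gene
    expression into components driven by sex differences in cell-type
    abundance versus within-cell-type regulatory change, using single-cell
    count matrices. Provides pseudobulk aggregation at whole-tissue and
    per-cell-type strata, a self-contained negative-binomial Wald test with
    median-of-ratios normalization and Benjamini-Hochberg correction,
    pseudocounted two-proportion tests of differential cell-type abundance,
    a four-way gene classification (bulk-only, bulk-and-cell, cell-only,
    unbiased), and group-aggregated dN/dS statistics with bootstrap
    confidence intervals and permutation contrasts. Includes a synthetic
    data generator with analytic ground truth and a command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
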