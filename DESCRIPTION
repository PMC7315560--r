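Package: mitoclock
Title: Epigenetic Mitotic Clocks from DNA Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates mitotic age (the cumulative number of stem-cell
    divisions, TNSC) and tissue-intrinsic stem-cell division rates (IR) from
    Illumina-style DNA methylation beta-value matrices. Implements the
    epiTOC2 stochastic model of replication-coupled de novo methylation gain
    (dyad-level recursion, closed-form trajectory and its first-order
    approximation), per-CpG parameter estimation by grid-multi-start
    non-linear least squares with rate-product filtering and (delta, IR)
    mode consensus, the earlier epiTOC pcgtAge score, and the comparator
    HypoClock score over solo-WCGW sites with age adjustment and dynamic
    range rescaling. Includes a synthetic-cohort generator with
    beta-distributed, age-heteroscedastic noise for parameter
    identifiability studies, literature turnover-rate converters, and a
    command-line interface over delimited-text matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    optparse,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
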