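Package: poolscreen
Title: Pooled shRNA Screen Analysis by Exact Negative Binomial Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled short-hairpin RNA (shRNA) dropout/enrichment
    screens read out by amplicon sequencing. Provides exact index-hairpin
    counting of demultiplexed reads into a hairpin-by-sample count matrix,
    a two-group exact test for negative binomial counts with a common
    dispersion estimated by conditional maximum likelihood, Benjamini-Hochberg
    false discovery rates, fold-change/FDR hit classification, MDS-based
    sample quality control, a single-hit limiting-dilution frequency
    estimator, and an expression-based candidate filter (CPM, TMM
    normalization, expressed-gene calls, probe collapse). A synthetic-screen
    generator produces FASTQ reads and count matrices with planted
    fold-changes and full ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
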