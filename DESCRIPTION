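Package: spikenorm
Title: Spike-In Benchmarking of miRNA-Seq Count Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare count-normalization strategies for small
    RNA sequencing data against a spike-in dilution ground truth. Implements
    eight normalization methods (counts-per-million, total-count scaling,
    upper-quartile, trimmed mean of M-values, median-of-ratios size factors,
    MA-plot linear regression, cyclic loess and quantile normalization),
    a synthetic-data generator emulating a 12x12 cyclic Latin-Square
    spike-in dilution experiment over a constant miRNA background, and the
    benchmarking metrics used to judge the methods: relative log expression,
    per-feature variance change, dilution-series bias regression,
    absolute fold-change bias, precision-recall of differential calls and
    fold-change concordance clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
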