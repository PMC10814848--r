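Package: hkgstab
Title: Reference Gene Stability Analysis for RT-qPCR Ct Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation of candidate housekeeping (reference) genes from
    RT-qPCR quantification-cycle (Ct) data. Implements the four stability
    algorithms in common use - geNorm M-values with stepwise exclusion,
    the NormFinder model-based variance estimator, BestKeeper descriptive
    statistics, and the comparative delta-Ct method - together with the
    geometric-mean rank consensus used to merge them into a single
    comprehensive ranking. Also quantifies the downstream impact of
    normalizer choice on delta-delta-Ct fold changes (worst-vs-best
    normalizer ratios and one-sample t-tests of fold changes against
    unity), and ships a synthetic Ct generator emulating a multi-donor,
    multi-culture-medium mesenchymal stromal cell study design for
    testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
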