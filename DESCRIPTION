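Package: serialdep
Title: Serial Dependence in Sequential Binary Diagnostic Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify serial dependence in sequences of binary
    (benign versus malignant) diagnostic decisions. Provides a signal-detection
    observer simulator with a similarity-tuned, lag-decaying attractive history
    bias; readers, validators and an exclusion pipeline for trial-record tables;
    consensus-malignancy and n-back similarity computation with configurable
    binning; signal-detection metrics (sensitivity, specificity, d-prime,
    criterion, error rate) with extreme-rate correction; n-back conditional
    analysis of those metrics against a future-trial baseline with permutation
    null distributions; and Gaussian tuning-curve fits whose peak quantifies the
    serial-dependence amplitude per lag.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
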