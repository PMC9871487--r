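Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained two-sample Mendelian randomization (MR) toolkit
    for GWAS summary statistics. Reads and harmonizes exposure/outcome
    association tables onto shared effect alleles, selects instrumental
    variables by p-value thresholding, greedy LD clumping and Steiger
    directionality filtering, and quantifies instrument strength with the
    F-statistic. Implements the Wald ratio, inverse-variance-weighted,
    MR-Egger, weighted-median, maximum-likelihood and robust adjusted
    profile score (MR-RAPS) causal estimators, plus a full sensitivity
    battery: Cochran's Q heterogeneity tests, the MR-Egger intercept
    pleiotropy test, an MR-PRESSO-style global/outlier/distortion
    simulation test, and leave-one-out analysis. A synthetic GWAS
    generator produces exposure/outcome summary-statistic pairs with known
    causal effects, configurable horizontal pleiotropy and LD-block
    structure, so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
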