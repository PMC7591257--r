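Package: ftmr
Title: One-Sample Mendelian Randomization of Calculated Free Testosterone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for phenome-wide one-sample Mendelian
    randomization of calculated free testosterone (CFT) in a male cohort:
    free-hormone calculation by mass-action binding (Vermeulen equation),
    genome-wide association scanning with variant quality control,
    instrument discovery with SHBG filtering and LD pruning, causal
    estimation by inverse-variance weighting with a full sensitivity suite
    (MR-Egger, MR-RAPS, MR-PRESSO, leave-one-out), and a weighted
    genetic-risk-score phenome scan with power-based outcome filtering and
    Bonferroni family-wise error control. A seeded synthetic-cohort
    simulator with configurable polygenic architecture, linkage
    disequilibrium, confounding and pleiotropy makes every stage testable
    without access to individual-level biobank data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
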