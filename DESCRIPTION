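Package: epiflint
Title: Case-Control Allelic Association and SF+FLINT Epistasis Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for candidate-gene case-control studies of biallelic SNPs:
    single-variant carriage association with exact Fisher p-values and Woolf
    confidence intervals, Hardy-Weinberg and pairwise linkage-disequilibrium
    screening, bounded exhaustive mining of multi-locus allelic-combination
    patterns with a minimality filter and a family-wise permutation null, the
    two-statistic SF+FLINT procedure for detecting epistasis in 2x2x2
    carriage-by-carriage-by-outcome tables (Synergy Factor with confidence
    interval plus an exact Fisher-like three-way interaction test), composite
    logistic risk models with ROC/AUC evaluation and discovery-to-replication
    transfer, and a synthetic case-control cohort simulator with plantable main
    effects, an epistatic pair, sex effects and linkage disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
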