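Package: famprs
Title: Polygenic Risk Score Penetrance and Sibling Recurrence Risk in Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multiplex family cohorts for a late-onset,
    liability-threshold disease (modelled on familial Alzheimer's disease),
    computes clumping+thresholding polygenic risk scores with and without the
    APOE region, and estimates penetrance by score quantile, discordant
    sibling-pair statistics, age-specific cumulative penetrance with
    permutation-based group comparisons, and liability-threshold sibling
    recurrence risk for probands above a score percentile.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
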