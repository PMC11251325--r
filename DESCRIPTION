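Package: tnddesign
Title: Design and Analysis of Test-Negative Vaccine Effectiveness Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Hypothesis tests and sample size calculations for test-negative
    design (TND) vaccine effectiveness studies analysed as 2x2
    vaccination-by-test-result tables. Provides one-sided Wald,
    continuity-corrected Wald, and score tests of the odds ratio; four
    sample size calculators (standard Wald, Fleiss-corrected Wald,
    case-control score, and a TND-adjusted score size that accounts for the
    random ratio of test-positives to test-negatives via a
    binomial-weighted power sum); and a Monte-Carlo simulator of TND and
    matched case-control studies under an all-or-none vaccine model with
    constant hazards, for estimating power, type-I error, zero-cell
    frequency and continuity-correction bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
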