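Package: bcsagree
Title: Multi-Rater Agreement Analysis for Feline Body Condition Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing agreement among multiple raters assigning
    9-point body condition scores (BCS) from visual assessment. Implements
    majority-vote consensus with a documented tie-break, closest-reference
    deviation statistics, ties-corrected Kendall's coefficient of concordance,
    Bland-Altman limits of agreement, Spearman correlation matrices with a
    subject-level bootstrap comparison of dependent overlapping correlations,
    diagnostic-category (ideal weight / overweight / obese) misclassification
    shift analysis, and a synthetic multi-rater cohort generator so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
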