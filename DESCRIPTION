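Package: medmapr
Title: Normalize Free-Text Medication and Reason-for-Use Records into
    Drug and Disease Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automation workflow for epidemiological survey data in which
    medications and the reasons for taking them are recorded as free text.
    Medication entries are screened against a supplement lexicon, spell-
    corrected by Levenshtein matching against a drug lexicon, resolved to a
    concept identifier and mapped to WHO ATC therapeutic classes (levels 1-3).
    Reason entries are spell-corrected word by word against a general
    dictionary, reduced to stems with a Paice/Husk (Lancaster) rule engine and
    grouped into organ-system disease categories through a stem dictionary,
    with a manual-review queue and an override mechanism for residual records.
    Includes a seeded synthetic-corpus generator with ground truth for
    evaluating recovery under controlled misspelling rates, and summary
    reporting of feature-set sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
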