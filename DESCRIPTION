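Package: assertnet
Title: Assertion Networks for In Silico Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds semantically consistent networks of subject-verb-object
    assertions from biomedical text and structured tables using curated
    concept vocabularies and relation lexicons, and derives candidate disease
    biomarkers by filtering the network for proteins expressed in affected
    brain regions, upregulated in disease, and linked to pathological
    hallmarks. Includes dictionary-based longest-match term recognition,
    within-sentence triple extraction with negation handling, curation and
    acceptance-sampling quality control, a seeded synthetic-corpus generator
    with gold annotations for benchmarking extraction, and the validation
    statistics used for candidate follow-up (one-way ANOVA from raw data or
    printed group summaries, Spearman rank correlation, and a Monte-Carlo
    Lilliefors normality check).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
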