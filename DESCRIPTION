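Package: aeselect
Title: Selection Criteria for Non-Systematic Adverse Events in Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how adverse-event (AE) selection criteria --
    rules that decide which spontaneously reported AEs from a randomized
    trial appear in a given report -- affect the harms evidence base.
    Represents per-arm AE frequency tables, parses and enumerates selection
    criteria built from a numerical threshold, a participant-group scope,
    and a between-group difference rule, applies single criteria or the
    full crossed grid to trials (percent-of-AEs-reported heat maps),
    detects discrepancies between a stated criterion and what a source
    actually reported, and quantifies by seeded simulation how
    criterion-based selective reporting biases Mantel-Haenszel pooled
    risk ratios and hides rare adverse events.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
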