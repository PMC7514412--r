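Package: esin
Title: Severity and Complexity Classification of Emergency Department Visits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a retrospective five-level Emergency Severity Index
    (ESI-N) for emergency department visit records abstracted in the style of
    the National Hospital Ambulatory Medical Care Survey (NHAMCS-ED). Visits
    are classified by a stepwise, fully configurable rule set driven by
    reason-for-visit codes, resuscitation flags, vital-sign extremes, pain
    level, and a count of diagnostic/therapeutic resources actually used.
    Includes readers for NHAMCS-like fixed-width and CSV visit files with
    sentinel-code normalization, design-based (Taylor-linearized)
    survey-weighted estimation of level shares, group means and
    outcome-by-level tables with reliability flagging, and a synthetic-record
    generator with planted ground-truth levels for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
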