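Package: survplan
Title: Personalized Survivorship Care Plans for Childhood Cancer Survivors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An offline engine for long-term follow-up after childhood and
    young-adult cancer. From a structured treatment summary (surgery,
    cumulative chemotherapy doses, radiotherapy fields and organ doses,
    transplantation, follow-up events) it evaluates a declarative guideline
    rule base under three-valued logic -- so that missing dosimetry degrades
    gracefully into propose-with-caveat behaviour -- and produces an auditable
    personalized surveillance plan. Companion modules schedule and track the
    resulting surveillance calendar (pauses, permanent stops, notifications,
    overdue detection), render harmonized treatment summaries, export
    pseudonymized cohort tables, assign area-deprivation quintiles, and
    generate synthetic survivor cohorts for testing and calibration.
    The shipped rule base is structurally conformant and clinically
    illustrative; it is not a medical product.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
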