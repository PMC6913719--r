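Package: commscreen
Title: Chronic Disease Screening Engine for Community Health Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening engine for community-based chronic disease events:
    per-participant cardiovascular disease (CVD) risk stratification from the
    Framingham 1991 five-year absolute-risk equation with Australian guideline
    clinical overrides, AUSDRISK-based diabetes risk with glycaemic overrides,
    chronic kidney disease risk composites, albuminuria and lifestyle
    risk-factor flags, care-gap assessment against guideline medication and
    treatment targets, aggregate event reporting with follow-up rates, a
    follow-up prioritisation sort for provider portals, and a seeded synthetic
    cohort generator calibrated to published community-screening prevalences
    so the whole pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
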