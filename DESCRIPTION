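Package: msaccrual
Title: Configurable Annotation of EDSS Disability Accrual in Relapsing
    Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects confirmed worsening events on the Expanded Disability
    Status Scale (EDSS) in longitudinal follow-up data of people with
    relapsing multiple sclerosis and classifies each event as
    relapse-associated worsening (RAW), progression independent of relapse
    activity (PIRA), PIRA with a relapse during the confirmation interval,
    or undefined worsening. Every definitional choice -- baseline handling
    (fixed or roving), minimal-increase rule, confirmation requirement,
    relapse-proximity window, re-baselining and event-merging rules -- is
    configurable, and the full grid of 1440 tested definition variants can
    be enumerated and applied to a cohort to quantify how definitional
    choices move event rates, event-type contributions and time to first
    event. Includes eligibility screening of raw registry-style records
    into follow-up periods, cohort-level summaries (Kaplan-Meier time to
    first event, per-type contributions to event counts and to total EDSS
    change), paired permutation tests between parameter choices, and a
    synthetic-cohort generator with ground-truth event labels for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
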