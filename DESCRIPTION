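Package: cpraid
Title: Guideline-Conformance Scoring of Simulated Cardiopulmonary Resuscitations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how closely resuscitation teams follow
    advanced life support timing guidelines in simulated cardiac arrests.
    Provides a timestamped event-log format for coded scenarios, twelve
    CPR performance metrics (no-flow fraction, compression depth and rate,
    times to first rhythm analysis and first shock, cycle-timing deviations,
    action counts, amiodarone timing), a 0/1/2 rubric with 15% margin bands
    aggregated into a per-team CPR performance score, the supporting
    statistics (ICC(A,1) reliability, normality-gated two-group comparisons
    with Cohen's d or rank-biserial effect sizes, Fisher exact tests, raw
    NASA-TLX workload, a two-group sample-size helper), a deterministic
    re-implementation of a tablet cognitive-aid timer/alert engine, and a
    seeded synthetic cohort generator so the full pipeline can be exercised
    without video-coded study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nortest,
    yaml,
    jsonlite,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
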