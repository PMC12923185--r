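Package: ppvplan
Title: Planning Research on Interaction Effects with the Positive
    Predictive Value
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Planning and audit toolkit for research on statistical
    interaction effects. Combines the positive predictive value (the
    post-study probability that a significant claim reflects a true
    effect) with pattern-of-means power analysis for balanced 2x2
    between-participants designs, a heuristic for eliciting the
    pre-study probability that a hypothesis is true, a sector grid that
    crosses interaction shape with that prior, and a seeded Monte-Carlo
    simulator of a research field that validates the analytic formulas
    empirically. Interaction power uses the exact noncentral-F
    distribution for the 1-df interaction contrast; sample-size search
    returns minimal balanced designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
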