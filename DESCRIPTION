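Package: ascotbws
Title: Best-Worst Scaling Valuation of the ASCOT-Carer Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving preference weights for the seven-attribute,
    four-level ASCOT-Carer instrument from profile-case best-worst scaling
    (BWS) experiments. Generates orthogonal main-effects plans for the
    experimental design, simulates synthetic respondent cohorts and exploded
    sequential best/worst choice data under a scale-heterogeneity multinomial
    logit (S-MNL) with position and learning effects, fits the exploded-choice
    models by maximum likelihood with cluster-robust (sandwich) inference,
    applies post-stratification taste adjustment, and normalises and anchors
    the estimated coefficients into a 0-1 social care-related quality-of-life
    index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
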