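Package: speedcog
Title: Scoring, Simulation and Norming of Web-Administered Speeded Cognitive Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level scoring machinery for two web-administered speeded
    cognitive tests: a stop-and-go switching task for executive functioning
    (median response times per trial type with a 70 percent accuracy validity
    filter) and a figure-matching test of perceptual speed (posterior
    time-limit scoring with outlier removal and balanced item-block
    randomization). Includes a synthetic-cohort generator with lognormal
    response latencies, careless-responder contamination and survey weights;
    device-type effect sizes (Cohen d with confidence intervals, Cohen q for
    age-correlation differences); distraction regressions with an age
    covariate; partial correlations; and survey-weighted age-group norms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
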