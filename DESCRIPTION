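Package: aversim
Title: Goal-Directed and Pavlovian Arbitration in Simulated Aversive Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an agent facing signalled-avoidance tasks in which a
    goal-directed planner (a learned stimulus-action-outcome model with
    softmax plan selection) and a Pavlovian reactor (an innate response whose
    vigour tracks learned stimulus value) compete for control of behaviour.
    Arbitration between the two controllers is a logistic function of
    instrumental ability, a weighted sum of the plan's expected value,
    specific and generalised controllability, Pavlovian value, and threat
    distance. Ships preset avoidance experiments covering goal-directed
    acquisition, Pavlovian interference, controllability effects, learned
    helplessness, and threat-distance modulation, with seeded, fully
    reproducible per-trial traces as tibbles and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
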