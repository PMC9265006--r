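Package: dottask
Title: Headless Engine for Touchscreen Dot-Task Training with Simulated
    Subjects
Version: 1.0.0
Authors@R:
    person("DotTask", "Developers", email = "dottask@example.org",
           role = c("aut", "cre"))
Description: A testable, hardware-free engine for operant touchscreen
    "dot task" training of the kind used for primate enrichment and
    cognition research. Implements the discrete-trial state machines for
    three shaping tasks (One Dot, Two Dot, Two Number Dot), a 95-session
    shaping curriculum with forced-choice trial interleaving, a 10-minute
    session runner with inter-trial intervals, feedback/reward event
    emission, durable CSV/JSONL trial and event logs, and the standard
    analyses: trials-per-minute engagement and block-wise choice accuracy
    with exact binomial tests against chance. Simulated subjects (ideal,
    random, stimulus-directed, and Rescorla-Wagner learners) stand in for
    animals and serve as the package's synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
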