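Package: heurigroup
Title: Fast-and-Frugal Heuristic Agents and Majority-Rule Group Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based Monte Carlo simulation of paired-comparison
    decision making with fast-and-frugal heuristics.  Options are generated
    from a linear-Gaussian cue model in named task environments that differ
    in the dispersion of cue validities; take-the-best and minimalist agents
    decide which of two options has the larger criterion value, and groups
    aggregate member decisions by simple majority rule.  The package
    implements cue-validity estimation, individual learning of cue search
    orders from samples, noisy cue perception, and study drivers that sweep
    group size, learning-sample size and information-error magnitude,
    reporting individual accuracy, group accuracy and group diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
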