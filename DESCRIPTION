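Package: eebae
Title: Exploration-Exploitation Bayesian Adaptive Estimation for
    Psychometric Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based Bayesian adaptive estimation for binary-response
    psychometric functions. Stimuli are selected by maximal mutual
    information between the parameter distribution and the upcoming binary
    response, with the information gain per trial bounded above by the
    current posterior entropy. An exploration-exploitation policy switches
    from information-maximal to uniform-random stimulus selection once the
    posterior entropy falls below a threshold, which preserves estimation
    accuracy while avoiding the per-trial information sweep. Includes a
    truncated log-parabola contrast sensitivity model, a probit gap
    acceptance model, a virtual-subject simulator, a replication harness,
    and a command-line interface driven by JSON configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
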