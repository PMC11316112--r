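Package: ebpmsim
Title: Faulty and Faultless Disagreement in Evidence-Based Policymaking
Version: 1.0.0
Authors@R: person("ebpmsim", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Simulates two agents who learn the unknown means of two Gaussian
    evidence streams by conjugate normal-normal updating, weight the streams
    differently (and possibly observe one stream with a systematic bias), and
    issue threshold-based policy recommendations. Provides a seeded paired
    Monte Carlo harness with configurable stream rates and reporting inertia,
    classification and aggregation of support, policy and uncertainty
    disagreement, an analytic posterior-uncertainty curve over stream weights,
    and an identifiability analysis asking whether a biased (faulty)
    configuration can be told apart from a weights-only (faultless) one from
    limiting beliefs alone. Includes a command-line driver with JSON configs
    and tidy CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
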