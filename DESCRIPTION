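Package: ecoaf
Title: Information-Theoretic Indicators of Ecosystem Stability, Resilience
    and Antifragility
Version: 0.1.0
Authors@R:
    person("Ecosystem Dynamics", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Metrics for ecosystem condition dynamics built on information
    theory: sliding-window Fisher information of a phase-space trajectory as a
    stability and regime-shift indicator, emergence/self-organization/complexity
    measures from discrete and permutation entropy, antifragility scoring via
    complexity change under perturbation (including a random Boolean network
    experiment and Jensen-gap convexity detectors), ascendancy and average
    mutual information of ecological flow networks, 1/f^beta spectral-exponent
    criticality classification, and harmonic-regression spectral-recovery time
    after disturbance.  Includes seeded synthetic generators emulating
    seasonal vegetation-index series with an abrupt disturbance and
    configurable recovery, colored noise, random Boolean networks and flow
    networks, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
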