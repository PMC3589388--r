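Package: stimplast
Title: Spike-Triggered Microstimulation Plasticity in a Thalamocortical
    Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven simulation of a layered thalamocortical spiking
    network with spike-timing-dependent plasticity under closed-loop
    (spike-triggered), random, and persistent-touch stimulation protocols,
    together with the full before/after spike-train analysis pipeline used
    to quantify stimulation-induced cortical plasticity: Gaussian-smoothed
    peristimulus time histograms and touch-response metrics, sliding-window
    Fano factors, shuffle-corrected unit-pair mutual information and
    ensemble multi-information, crosscorrelograms, and session-level
    percentage-change statistics.  A synthetic-session generator with
    injectable ground-truth effect sizes makes every analysis stage
    testable without the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
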