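Package: nmsim
Title: Delay-Coupled Heterogeneous Neural Mass Simulation of Small Cortical Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates small clusters of delay-coupled, heterogeneous neural
    mass oscillators of the Wilson-Cowan / Jansen-Rit type, in which each
    cortical area is a critically damped three-population oscillator driven by
    noise, wave-modulated pulse-train stimuli and the weighted, delayed outputs
    of linked areas.  Provides a complementary-error-function voltage-to-rate
    transform derived from a distribution of synaptic weights, a synthetic
    generator for prefrontal-cortex-like weighted connectomes, a fixed-step
    fourth-order Runge-Kutta delay integrator, local-field-potential band-power
    and dynamical-transition analyses, and reproducible stimulation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
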