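Package: tumorCTL
Title: Hybrid Agent-Based and Delay-Differential-Equation Simulation of
    Protective Anti-Tumor CTL Immunity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the elimination of an incipient solid tumor by
    vaccine-primed memory cytotoxic T lymphocytes (CTLs) using a
    two-compartment hybrid model: an off-lattice probabilistic 3-D
    agent-based model of tumor cells and CTLs inside a bounded spherical
    tissue region, coupled at every time step to a deterministic
    difference-equation model of antigen presentation and CTL expansion in
    the draining lymph node (with a method-of-steps delay-differential
    reference solver). Also provides a deterministic surface-limited
    kill ODE with finite-time tumor extinction, outcome summaries
    (extinction time, maximum tumor burden, relapse counting, cube-root
    decline regression), and a one-at-a-time Spearman sensitivity sweep
    harness, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    deSolve,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
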