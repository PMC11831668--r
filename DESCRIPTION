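Package: kmcdown
Title: On-the-Fly Rate-Constant Downscaling for Stiff Stochastic Reaction
    Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Exact event-driven simulation of well-mixed mass-action reaction
    networks with the Modified Next Reaction Method, using one random-number
    stream per slow reaction channel and a shared stream for the fast channels
    so that common-random-number replicates can be generated from saved
    snapshots.  On top of the simulator, an on-the-fly controller reduces the
    rate constants of fast quasi-equilibrated reversible reactions: it
    measures how computational cost and an interarrival-time error norm scale
    with the downscale factor, fits power laws to both, and picks the factor
    minimising a weighted cost-error objective, subject to quasi-equilibrium,
    frequency-ordering, time-scale-separation, error-saturation and absolute/
    relative error gates.  Includes a stiff biochemical oscillator benchmark,
    spectral-density and probability-mass-function validation tools, and
    programmatic toy-network and synthetic cost/error fixtures.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
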