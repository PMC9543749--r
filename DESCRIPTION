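Package: invasibility
Title: Invasion Probabilities Under Demographic and Environmental
    Stochasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies invasibility, the probability that a population
    starting from n individuals reaches a target abundance nf before going
    extinct, in a community subject to both demographic and environmental
    stochasticity.  Implements two closed-form invasion formulae (a
    diffusion approximation and a large-deviations WKB formula built on the
    two-destination jump reduction), the moment-regression procedure that
    infers their parameters from abundance time series sampled at the
    environmental dwell time, an exact backward-Kolmogorov solver for small
    state spaces, and individual-based stochastic simulators (discrete-time
    lottery, its Moran analogue, and a Leslie-Gower tree/sapling model)
    with Monte-Carlo estimation of invasion probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
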