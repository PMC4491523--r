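Package: pulsereduce
Title: Nonlinear 1D Pulse-Wave Simulation and Windkessel Reduction of
    Arterial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates nonlinear one-dimensional blood pressure and flow
    waves on branched networks of tapered elastic vessels with
    three-element windkessel outflow models, and reduces peripheral
    branches of such networks into equivalent lumped (windkessel) models
    that preserve the net peripheral resistance and total compliance of
    the original network. Includes a conservative finite-volume solver
    with characteristic junction and boundary coupling, stand-alone two-
    and three-element windkessel dynamics, generation-trimming and
    pairwise peripheral lumping reduction schedules, a hypertensive
    network transformation, six relative waveform-error metrics, and
    deterministic generators of physiologically plausible arterial-tree
    fixtures including 55- and 67-artery-style systemic trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
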