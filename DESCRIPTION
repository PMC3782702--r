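Package: actinf
Title: Active Inference for Discrete Markov Decision Games
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discrete-state active inference for Markov decision games.
    Implements a generative model over hidden states, control states and
    precision; policy values as negative Kullback-Leibler divergences from
    predicted final-state distributions to a goal prior (decomposable into
    an entropy bonus and expected utility); and the coupled variational
    updates for perception, action selection and precision, iterated to
    convergence within a closed action-perception loop. Ships a fully
    parameterized "limited offer" waiting game with time-dependent hazard
    rates, together with analyses of choice latencies, precision dynamics
    (with exponential-kernel deconvolution), temporal discounting and
    marginal utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
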