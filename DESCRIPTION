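Package: herdabort
Title: Markov Replacement Model for Dairy Herds with Abortion Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monthly Markov chain model of a dairy cow herd for evaluating
    voluntary replacement (culling) policies for open cows. Implements the
    classic three-dimensional cow state space (parity, gestation month, month
    in lactation) and an extension that tracks abortion history (rebreeding
    and new-lactation abortions) as a fourth state dimension, with their
    effects on milk yield and involuntary culling risk. Provides sparse
    transition-matrix construction, stationary herd-structure solution by
    direct sparse solve or power iteration, per-cow-per-month bioeconomic
    evaluation (income over feed cost, calf, salvage, replacement,
    insemination and veterinary flows), optimization of the voluntary-culling
    month by policy sweep, a non-pregnancy sensitivity analysis, and a
    Monte-Carlo cohort simulator used as an independent validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
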