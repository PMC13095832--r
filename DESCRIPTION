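Package: cutevo
Title: Macroevolution of Cutting Preferences in Leaf-Cutting Ants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-trait macroevolution toolkit built around the
    cutting-preference dataset of leaf-cutting ants (Acromyrmex, Amoimyrmex,
    Atta). Fits the k-state Mk model with equal rates by maximum likelihood
    (Felsenstein pruning), reconstructs marginal ancestral states at every
    node by the re-rooting method, samples stochastic character maps by
    endpoint-conditioned path simulation (uniformization), and summarises
    trait accumulation through time on a uniform grid from root to present.
    Ships the compiled species-by-preference table as a plain-text fixture
    and a birth-death chronogram simulator with known-truth Mk histories so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
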