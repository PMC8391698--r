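Package: bayesmech
Title: Bayesian Mechanics of Markov Blankets at Nonequilibrium Steady State
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for constructing and simulating stochastic dynamical
    systems with a prescribed nonequilibrium steady state, using the
    Helmholtz decomposition of the stationary flow into dissipative and
    solenoidal components.  Provides exact algebraic checks for Markov
    blanket partitions of Gaussian systems (sparsity of the precision and
    solenoidal-coupling matrices and the implied Jacobian flow
    constraints), closed-form variational free energy decompositions with
    evidence bounds and gradient-flow equivalences, and a demonstration
    simulator of distance-coupled stochastic Lorenz "macromolecules" with
    canonical-correlation, synchronisation-manifold and event-related
    averaging analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
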