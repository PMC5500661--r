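Package: finitewave
Title: Finite-Size Effects on Traveling Waves in Neural Field Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying intrinsic finite-size noise on traveling
    wave solutions of voltage-based neural field equations. Implements the
    full model hierarchy: a continuous-time Markov chain for the activity of
    a network of finite neuronal populations with balance-seeking jump
    rates, its mean-field ordinary differential equation limit, a Newton
    collocation solver for the monotone traveling wave profile and speed of
    the continuum neural field equation, the diffusion (linear noise)
    approximation around the wave with cutoff coefficients, and the
    continuum stochastic neural field equation driven by a spatially
    correlated Q-Wiener process. Includes numerical experiments verifying
    the law of large numbers, the martingale central limit theorem, and the
    lattice-to-continuum convergence at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
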