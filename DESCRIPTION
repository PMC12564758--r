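Package: pathentropy
Title: Path Entropy and Maximum-Entropy Identification of Compartmental
    Systems in Equilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Information-theoretic analysis of open compartmental systems in
    equilibrium.  A compartmental system dx/dt = B x + u is viewed through
    the absorbing continuous-time Markov chain of a single particle, which
    yields the Shannon entropy of the particle's full path through the
    system, entropy rates per unit time and per jump, and a macroscopic
    system entropy.  The package provides the closed forms and their
    jump/sojourn decomposition, a particle-path simulator that serves as a
    Monte-Carlo cross-check, maximum-entropy model constructors under
    transit-time and steady-state constraints, structural model
    identification from transfer-function coefficients by multi-start
    constrained maximization of the entropy rate, and builders for two
    classic carbon-cycle box models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
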