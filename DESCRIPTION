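Package: mplearn
Title: Metaprogram Search for Learning List Functions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian program induction over first-order term rewriting
    systems for functions on lists of natural numbers. Hypotheses are
    metaprograms: compositions of program-transforming metaprimitives
    (memorization, recursion introduction, anti-unification, and friends)
    that reduce, given data, to ordinary rewrite programs. The package
    provides the typed term language and rewriting semantics, grammar-based
    priors over metaprograms and programs, a prefix-noise likelihood,
    Metropolis-Hastings search with parallel tempering and an online
    trial-by-trial protocol, a description-length enumeration baseline with
    a win-stay/lose-shift policy, a benchmark generator for list-function
    concept-learning experiments, and an experiment harness with
    acquisition and accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
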