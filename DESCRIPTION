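Package: domainyield
Title: Yield Modeling and Design Optimization for Protein Domain Solubility Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Probabilistic planning of large-scale soluble-protein-domain
    production. Estimates domain- and boundary-prediction success
    probabilities from pilot fragment-solubility screens via a 2x2
    contingency decomposition, computes the probability that at least one
    of N tested fragments of a soluble domain is soluble under
    with-replacement (binomial) and without-replacement (hypergeometric)
    sampling, evaluates the expected number of soluble domains under a
    fixed total cost, and locates the cost-optimal number of fragments to
    test per predicted domain. Includes a seeded Monte-Carlo simulator and
    synthetic fragment-table generator for validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
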