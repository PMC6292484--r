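Package: fossiltrait
Title: Bayesian Inference of Quantitative Trait Evolution on Phylogenies
    with Fossil Tips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates rates, directional trends and ancestral states of
    continuous traits on time-calibrated phylogenies that include extinct
    (non-contemporaneous) tips. Trait change follows Brownian motion with a
    drift term; rates and trends may shift across clades, and the number and
    placement of shifts is sampled with a birth-death MCMC while ancestral
    states are drawn by a conjugate Gibbs sampler. Includes a birth-death
    tree and trait simulator and an accuracy harness (MAPE, MAE, R-squared,
    shift-count recovery) for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
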