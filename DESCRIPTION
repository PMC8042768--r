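Package: selon
Title: Spatially Explicit Stabilizing-Selection Substitution Models for
    Ultraconserved Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a Wright-Fisher mutation-selection-drift substitution model
    (SelON) to ultraconserved elements (UCEs) on fixed rooted phylogenies.
    Each UCE receives a Gaussian spatial profile of sensitivity to stabilizing
    selection toward an estimated optimal nucleotide sequence, giving every
    site its own non-reversible rate matrix and equilibrium frequencies.
    Includes a compiled Felsenstein pruning engine, a four-stage hill-climbing
    maximum-likelihood optimizer, sequence simulation under SelON and GTR+Gamma
    (generalized Laguerre rate categories), AICc model comparison, UCE-level
    bootstrap of topology support, parsimony-guided alignment trimming,
    model-adequacy simulation, and site-wise support profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
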