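Package: claderich
Title: Random Clade Sampling and the Causes of Species Richness Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether species richness differences among clades of a
    time-calibrated phylogeny are explained by clade age or by net
    diversification rate. Samples non-nested clades uniformly at random
    (optionally stratified), computes crown and stem ages and in-tree
    richness, estimates net diversification with crown- and stem-group
    method-of-moments estimators under an assumed relative extinction
    fraction, and fits replicated ordinary and phylogenetic generalized
    least-squares regressions with maximum-likelihood Pagel's lambda.
    Includes a constant-rate birth-death clade-forest simulator with known
    generating parameters, artifact injection (polytomies, zero-length
    branches, incomplete sampling) and experiments for subsampling
    robustness and described-richness substitution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
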