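Package: admixabc
Title: Forward-in-Time Admixture Simulation and Machine-Learning ABC
    Inference of Admixture Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-centred Wright-Fisher simulation of a two-source
    admixed population over 21 generations under four competing historical
    scenarios (two-pulse or recurring gene flow from an African and a
    European source), a 42-statistic summary of genetic diversity and
    individual admixture patterns (allele-sharing dissimilarities, metric
    MDS admixture projections, Weir-Cockerham Fst, f3-admixture),
    Random-Forest Approximate Bayesian Computation scenario choice and
    Neural-Network ABC joint posterior parameter estimation, and a
    permutation test for ancestry excess within long runs of homozygosity
    intersected with local-ancestry tracks. Includes a synthetic-data
    module generating source allele-frequency spectra with controlled
    divergence, pseudo-observed admixed datasets with known ground truth,
    and ancestry/ROH fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    nnet,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
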