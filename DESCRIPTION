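Package: pikemix
Title: Microsatellite Diversity and Hybrid-Class Assignment in Pike Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for diploid codominant microsatellite genotypes in
    mixed southern/northern pike (Esox cisalpinus / E. lucius) populations:
    GENEPOP input/output, marker validation (Hardy-Weinberg and linkage
    disequilibrium exact tests with Markov-chain Monte Carlo evaluation,
    cumulative-binomial excess checks, Benjamini-Yekutieli false-discovery-rate
    control, maximum-likelihood allelic-dropout correction, FDIST-style
    F_ST-outlier scan), within-population diversity and between-population
    differentiation (allelic richness by rarefaction, unbiased heterozygosity,
    Weir-Cockerham theta, Jost's D, exact G tests), linkage-disequilibrium
    effective population size, multinomial gamete-sampling simulation of hybrid
    genotypic classes, a forward-time hierarchical island simulator, Bayesian
    MCMC and expectation-maximisation hybrid assignment, discriminant analysis
    of principal components, and threshold-based power evaluation of hybrid
    detection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
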