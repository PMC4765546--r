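Package: mixmating
Title: Mating-System and Population-Structure Analysis for Partially Selfing Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise mixed mating systems of diploid plants from
    co-dominant multilocus genotypes (microsatellites). Implements
    maximum-likelihood estimation of population selfing rates from the joint
    distribution of heterozygosity across loci (robust to null alleles), a
    hierarchical logit-normal model comparing selfing-rate distributions
    between ecotypes via likelihood-ratio tests, a correlated mixed-mating
    model for progeny arrays (outcrossing rate, correlation of selfing and of
    paternity, biparental inbreeding), Weir-Cockerham and hierarchical
    F-statistics with permutation tests and isolation-by-distance analysis,
    and temporal-method variance effective population size. Seeded synthetic
    genotype generators reproduce the statistical structure every estimator
    assumes, for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    geosphere,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
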