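Package: msatpop
Title: Microsatellite Population Genetics: Diversity, Bottlenecks, Effective Size and Stock Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for co-dominant microsatellite genotype data: file input
    and output (tabular, GenePop, STRUCTURE dialects), per-locus diversity
    statistics (Na, Ho, He, PIC, Fis) with exact Hardy-Weinberg and genotypic
    linkage-disequilibrium tests, heterozygosity-excess bottleneck tests under
    the IAM, SMM and TPM mutation models with the Garza-Williamson M-ratio,
    linkage-disequilibrium effective population size with jackknife confidence
    intervals and heterozygosity-decay threat classification, differentiation
    statistics (Weir-Cockerham FST, standardized F'ST, Jost's D, AMOVA,
    exact G-tests), admixture-model Bayesian clustering with Evanno and
    Puechmaille K selection, a discriminant analysis of principal components,
    and synthetic-data generators (two-stock admixture panels and a forward
    Wright-Fisher simulator) for method validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
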