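Package: rvstrat
Title: Rare-Variant Association Tests under Fine-Scale Population Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how fine-scale
    population stratification affects gene-based rare-variant association
    tests. Provides a two-deme coalescent simulator (discrete-time
    Wright-Fisher recent history with migration feeding an ancestral
    Hudson coalescent), nine gene-based association statistics (CAST, Sum,
    weighted Sum variants, adaptive Sum, KBAC, SKAT, SKAT-O, PODKAT,
    DoEstRare) with several minor-allele-frequency weighting systems,
    analytic mixture-of-chi-square and adaptive permutation significance,
    two PCA-based stratification corrections, Weir-Cockerham FST and
    genotype PCA on pruned common variants, and a scenario harness that
    estimates type-I error and power with binomial confidence bands.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
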