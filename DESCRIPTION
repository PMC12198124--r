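Package: bsfparentage
Title: SNP-Based Parentage Assignment for Black Soldier Fly Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, marker quality control and likelihood-based parentage
    assignment for multigeneration full-sib black soldier fly (Hermetia
    illucens) breeding populations. Generates synthetic pedigrees and
    genotypes matching a two-colony, twelve-family, three-generation design;
    applies an auditable SNP and sample filter cascade (minor allele
    frequency, depth, missingness, Hardy-Weinberg exact test, Mendelian
    error, linkage-disequilibrium pruning); computes marker informativeness
    statistics (heterozygosity, polymorphism information content,
    non-exclusion probabilities, F-statistics); and performs error-aware
    LOD-score parentage assignment with Monte-Carlo calibrated critical
    thresholds at relaxed and strict confidence levels under configurable
    candidate relatedness and inbreeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
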