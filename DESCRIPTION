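Package: recselsim
Title: Stochastic Simulation of Recurrent Selection with Overlapping or
    Discrete Generations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Stochastic simulation of long-term recurrent selection in a
    diploid crop species, comparing overlapping against discrete breeding
    generations under phenotypic, genomic truncation, and genomic optimum
    contribution selection. Provides founder-genome generation with exact
    identity-by-descent tracking, meiosis, crossing and doubled-haploid
    production, additive trait architectures with year and
    genotype-by-year effects under compound symmetry, RR-BLUP genomic
    prediction with REML variance components, truncation and optimum
    contribution selection under an inbreeding-rate constraint, a
    single-cohort recurrent mass-selection pipeline and a multi-stage
    doubled-haploid yield-trial pipeline, and the response metrics
    (genetic gain, genetic variance, selection error bias and its
    year/genotype-by-year/plot decomposition, genomic inbreeding,
    selection accuracy, mean parental age) together with an experiment
    runner for factorial scenario grids and timepoint contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
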