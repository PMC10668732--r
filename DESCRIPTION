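Package: merinosim
Title: Stochastic Simulation of Sheep Breeding Programs with
    Genotype-by-Environment Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of a closed sheep breeding
    program with overlapping generations, modelled on the German Merino
    herdbook population. Simulates diploid founder genomes, meiosis with
    Haldane recombination, a multi-trait additive QTL architecture with
    genotype-by-environment interaction expressed as a genetic correlation
    between field- and station-recorded fattening traits, scenario-specific
    progeny-testing schemes, multi-trait pedigree BLUP evaluation via
    Henderson's mixed-model equations with a sparse A-inverse, and truncation
    selection on a total merit index. Reports genetic gain in genetic standard
    deviations, EBV accuracy, mean kinship, and genetic variance per breeding
    cycle, with paired scenario contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
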