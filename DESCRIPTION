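Package: ryegrassGS
Title: Stochastic Simulation of Genomic and Phenotypic Selection in
    Perennial Ryegrass Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates commercial perennial ryegrass (Lolium perenne L.)
    breeding programs as overlapping 12-year cycles of synthetic-variety
    (polycross) breeding, comparing conventional phenotypic selection with
    genomic selection entry points. Provides founder-genome simulation by
    gene dropping through a long historical population (Poisson
    recombination, recurrent mutation, MAF-filtered SNP/QTL panels),
    pleiotropic multi-trait architectures calibrated to plot
    heritabilities, family and polycross mating operations, plot-level
    allele-dosage genotyping, Bayesian ridge regression marker-effect
    estimation by Gibbs sampling, and metrics for cumulative genetic gain,
    selection accuracy, additive-variance erosion, heterozygosity and
    linkage-disequilibrium decay.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
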