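Package: sibnb
Title: Effective Number of Breeders from Sibship Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for evaluating sibship-based
    estimators of the effective number of breeders (Nb) in hatchery-style
    populations. Simulates predominantly monogamous hatchery pedigrees with
    male reuse and cross-contamination, drops biallelic SNP genotypes with
    genotyping error through the pedigree, reconstructs sibships from
    offspring genotypes alone by maximising a full likelihood under an
    assumed mating system via simulated annealing, and estimates Nb by the
    sibship-assignment (SA) method with a nonrandom-mating correction and by
    parentage-without-parents (PwoP, a Crow-Denniston family-size variant).
    Includes the evaluation designs used to benchmark the estimators: dyad
    confusion matrices, subsampling bias with percent root-mean-squared bias,
    and SA-versus-PwoP concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
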