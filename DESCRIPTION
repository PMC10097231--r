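Package: plumprint
Title: SSR Fingerprinting and Genetic Diversity Analysis for Polyploid Plum Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dominant-scored microsatellite (SSR)
    genotypes of polyploid crops such as hexaploid European plum (Prunus
    domestica). Provides per-locus diversity statistics for dosage-unknown
    data (observed heterozygosity as the multi-allele accession fraction,
    dominant-marker polymorphism information content), common/unique/rare
    allele classification between accession groups, minimal discriminating
    marker-set selection with an exhaustive oracle, UPGMA dendrograms with
    bootstrap support on binary band matrices, a STRUCTURE-style Bayesian
    admixture Gibbs sampler for ploidy-6 data with missing-slot (-9) coding,
    Evanno delta-K model selection, and a synthetic hexaploid genotype
    generator with group structure, pedigree crosses and fragment-size
    jitter for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
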