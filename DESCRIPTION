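Package: ldne
Title: Linkage-Disequilibrium Effective Population Size, Drift Divergence
    Times and UPGMA Trees from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic inference from dense autosomal SNP genotypes:
    reads PLINK binary genotypes, applies array quality-control filters
    (missingness, minor allele frequency, Hardy-Weinberg equilibrium),
    estimates effective population size (Ne) through time from mean pairwise
    r-squared within overlapping recombination-distance categories via the
    Sved relationship, summarises long-term Ne as a harmonic mean with
    leave-one-chromosome-out jackknife confidence intervals, computes
    pairwise Weir-Cockerham (1984) FST, converts FST and Ne to drift
    divergence times T = ln(1-FST)/ln(1-1/(2*Ne)), and summarises divergence
    as ultrametric UPGMA trees in years. A forward Wright-Fisher simulator
    with recombination and a two-population drift-split simulator provide
    genotype data with known demographic truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
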