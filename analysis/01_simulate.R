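#!/usr/bin/env Rscript
# Generate the two synthetic study panels used throughout the analysis:
#  (a) a constant-Ne Wright-Fisher panel (Ne = 500, 100 diploids, 5
#      chromosomes at array-like marker density) for the LD-based Ne
#      trajectory, written as a PLINK trio plus a separate genetic-map file
#      (genetic positions stripped from the .bim so the map-attachment step
#      is exercised downstream);
#  (b) a two-population drift split (Ne = 1000 per branch, T = 100
#      generations, 20,000 unlinked loci) for FST and divergence dating.

library(ldne)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

## (a) constant-Ne panel ------------------------------------------------------
sc <- sim_scenario(n_chromosomes = 5, loci_per_chr = 300, chr_length_cm = 1.5,
                   demography = list(type = "constant", ne = 500),
                   sample_n = 100, seed = 101)
sim <- sim_wright_fisher(sc)
g <- sim$genotypes
cat(sprintf("constant-Ne panel: %d samples x %d sites, true Ne = 500\n",
            n_samples(g), n_sites(g)))

map <- genetic_map(chrom = g$sites$chrom, bp = g$sites$bp, cm = g$sites$cm)
write_genetic_map(map, "results/data/constant_ne500.map.txt")
g$sites$cm <- NA_real_
write_plink(g, "results/data/constant_ne500")
jsonlite::write_json(sim$truth["scenario"], "results/data/constant_ne500.truth.json",
                     auto_unbox = TRUE, pretty = TRUE, force = TRUE)

## (b) drift split panel -------------------------------------------------------
split <- sim_split_drift(branch_ne = 1000, t_split = 100, n_loci = 20000,
                         sample_n = 50, seed = 102)
write_plink(split$genotypes, "results/data/split")
jsonlite::write_json(
  split$truth[c("branch_ne", "t_split", "n_loci", "sample_n", "seed",
                "expected_fst")],
  "results/data/split.truth.json", auto_unbox = TRUE, pretty = TRUE)
cat(sprintf("split panel: 2 x %d samples, %d loci, expected FST = %.4f\n",
            split$truth$sample_n, split$truth$n_loci,
            split$truth$expected_fst))
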