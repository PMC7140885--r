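#!/usr/bin/env Rscript
# Quality control of the constant-Ne panel: attach the genetic map, then
# apply the array filters (10% individual and site missingness, HWE
# p < 1e-4). For the LD work the MAF floor is raised to 0.05 - rare
# alleles carry little pairwise-r2 information and bias Ne upward.

library(ldne)

g <- read_plink("results/data/constant_ne500")
map <- read_genetic_map("results/data/constant_ne500.map.txt")
g <- attach_genetic_map(g, map)

qc <- apply_qc(g, mind = 0.1, geno = 0.1, maf_min = 0.05, hwe_alpha = 1e-4)
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_qc_report(qc$report, "results/qc/removals.tsv", "results/qc/summary.json")
write_plink(qc$genotypes, "results/qc/constant_ne500_qc")

cat(sprintf("QC: %d -> %d individuals, %d -> %d sites\n",
            n_samples(g), n_samples(qc$genotypes),
            n_sites(g), n_sites(qc$genotypes)))
print(qc$report)
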