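#!/usr/bin/env Rscript
# Ultrametric UPGMA summaries of divergence times.
#
# First a closed-form demonstration: four populations with a known nested
# history (P1,P2 split 50 generations ago; their ancestor split from
# (P3,P4) 400 generations ago; P3,P4 split 150 generations ago; Ne = 1000
# throughout) are converted to expected pairwise FST by drift accrual, then
# back to a divergence-time matrix, and UPGMA must recover the nested
# structure with node heights at half the pairwise divergence times (the
# classic d/2 merge-height convention). Second, the tree of the simulated
# split panel.

library(ldne)

ne <- 1000
gens <- c(P1P2 = 50, P3P4 = 150, deep = 400)
labels <- paste0("P", 1:4)
t_mat <- matrix(gens["deep"], 4, 4, dimnames = list(labels, labels))
t_mat["P1", "P2"] <- t_mat["P2", "P1"] <- gens["P1P2"]
t_mat["P3", "P4"] <- t_mat["P4", "P3"] <- gens["P3P4"]
diag(t_mat) <- 0
fst <- fst_from_divergence(t_mat, ne)
diag(fst) <- 0

div <- divergence_matrix(fst, setNames(as.list(rep(ne, 4)), labels),
                         generation_years = 25)
tree <- upgma_tree(div)
dir.create("results/tree", showWarnings = FALSE, recursive = TRUE)
to_newick(tree, "results/tree/known_history_upgma.nwk")
depth <- max(tree_leaf_depths(tree))
cat("known-history tree:", to_newick(tree), "\n")
cat(sprintf(
  "root height %.0f years (expected %.0f = 400 generations x 25 / 2)\n",
  depth, gens["deep"] * 25 / 2))
stopifnot(abs(depth - gens["deep"] * 25 / 2) < 1e-6)

split_years <- read_square_tsv("results/divergence/years.tsv")
tree2 <- upgma_tree(split_years)
to_newick(tree2, "results/tree/split_panel_upgma.nwk")
cat("split-panel tree:", to_newick(tree2), "\n")
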