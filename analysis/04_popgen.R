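#!/usr/bin/env Rscript
# Stage 4: PAV-based population structure.
#
# Pairwise Hamming distances between samples on the binary matrix, a
# neighbor-joining tree written as Newick, and a PCA of the mean-centred
# gene columns. In this single-population simulation the cohort should
# look homogeneous: no deep splits, modest variance on PC1.

suppressPackageStartupMessages(library(pavpipe))

pav <- read_pav_matrix("results/pav/pav_matrix.tsv")
dir.create("results/popgen", recursive = TRUE, showWarnings = FALSE)

d <- pav_distance(pav)
write.table(cbind(sample_id = rownames(d), as.data.frame(d)),
            "results/popgen/distance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("mean pairwise PAV distance %.4f (max %.4f)\n",
            mean(d[upper.tri(d)]), max(d)))

tree <- neighbor_joining(d)
ape::write.tree(tree, "results/popgen/nj_tree.nwk")
cat(sprintf("neighbor-joining tree over %d samples written\n",
            length(tree$tip.label)))

pca <- pav_pca(pav, k = 2)
write.table(cbind(sample_id = rownames(pca$scores), as.data.frame(pca$scores)),
            "results/popgen/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of PAV variance\n",
            100 * pca$var_explained[1], 100 * pca$var_explained[2]))
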