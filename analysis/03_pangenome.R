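#!/usr/bin/env Rscript
# Stage 3: pangenome frequency classification.
#
# Classifies every called gene into core / softcore / shell / cloud by its
# presence frequency, tabulates per-sample and per-chromosome presence,
# and lists the dispensable genes with their annotation categories.

suppressPackageStartupMessages(library(pavpipe))

genes <- parse_gff3("scratch/study/annotation.gff3")
pav <- read_pav_matrix("results/pav/pav_matrix.tsv")
pg <- pangenome_summary(pav)
print(pg)

dir.create("results/pangenome", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(class = names(pg$class_counts),
                       count = as.integer(pg$class_counts),
                       pct = as.numeric(pg$class_pct)),
            "results/pangenome/classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pg$per_sample, "results/pangenome/per_sample.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(per_chromosome_distribution(pav, genes),
            "results/pangenome/per_chromosome.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
disp <- dispensable_list(pav, genes)
write.table(disp, "results/pangenome/dispensable_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d dispensable genes; category mix: %s\n", nrow(disp),
            paste(names(attr(disp, "category_pct")),
                  sprintf("%.1f%%", attr(disp, "category_pct")),
                  sep = " ", collapse = ", ")))
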