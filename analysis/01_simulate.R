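#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Builds the default design — 150 animals, 500 genes on 5 autosomes with a
# ~94% core pangenome, 20x Poisson exonic depth — plus one planted causal
# gene (presence frequency 0.3, effect 2 residual s.d. on trait T01).
# Raw per-sample BedGraphs and the GFF3 go under scratch/study (large,
# regenerable); the truth tables are copied to results/study.

suppressPackageStartupMessages(library(pavpipe))

design <- sim_design(seed = 101L,
                     causal = data.frame(trait = "T01", frequency = 0.3,
                                         beta = 2))
sim <- simulate_pav_study(design, dir = "scratch/study")

dir.create("results/study", recursive = TRUE, showWarnings = FALSE)
invisible(file.copy(file.path("scratch/study",
                    c("truth_matrix.tsv", "phenotypes.tsv", "manifest.json")),
          "results/study", overwrite = TRUE))
write.table(data.frame(gene_id = names(sim$class), class = sim$class),
            "results/study/truth_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("simulated %d genes x %d samples (seed %d)\n",
            design$n_genes, design$n_samples, design$seed))
cat(sprintf("planted classes: %s\n",
            paste(names(design$class_quotas), design$class_quotas,
                  sep = "=", collapse = ", ")))
cat(sprintf("causal gene: %s (frequency %.2f, beta %.1f sd) on %s\n",
            sim$causal$gene_id, sim$causal$frequency, sim$causal$beta,
            sim$causal$trait))
cat("raw depth/annotation in scratch/study; truth tables in results/study\n")
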