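#' Pipeline run configuration
#'
#' @param annotation Path to the GFF3 annotation.
#' @param depth_dir Directory of per-sample `<sample>.bedgraph` files.
#' @param phenotypes Optional path to a long-format phenotype TSV
#'   (`sample_id`, `trait`, `pta`, `reliability`); required for the
#'   association stage.
#' @param out_dir Output directory.
#' @param min_cov,lost_cutoff PAV-calling parameters (see [pav_params()]).
#' @param maf_threshold MAF filter for the association stage.
#' @param allowed_chromosomes Optional chromosome whitelist (e.g. the
#'   autosomes) applied to the annotation before calling.
#' @param pca_k Number of principal components to report.
#' @param stages Which downstream stages to run after PAV calling.
#' @return A `run_config` list.
#' @export
run_config <- function(annotation, depth_dir, phenotypes = NULL, out_dir,
                       min_cov = 5L, lost_cutoff = 0.2, maf_threshold = 0.05,
                       allowed_chromosomes = NULL, pca_k = 2L,
                       stages = c("pangenome", "popgen", "association")) {
  stages <- match.arg(stages, c("pangenome", "popgen", "association"),
                      several.ok = TRUE)
  structure(list(annotation = annotation, depth_dir = depth_dir,
                 phenotypes = phenotypes, out_dir = out_dir,
                 min_cov = min_cov, lost_cutoff = lost_cutoff,
                 maf_threshold = maf_threshold,
                 allowed_chromosomes = allowed_chromosomes,
                 pca_k = pca_k, stages = stages),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()]'s arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the PAV analysis pipeline
#'
#' Executes annotation parsing, depth ingestion, PAV calling and the
#' enabled downstream stages in order, writing every tabular output plus
#' a manifest (configuration echo, package version, per-stage row counts,
#' MD5 checksum of every file). Re-running the same configuration on the
#' same inputs reproduces identical outputs.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list of the in-memory stage results
#'   (`genes`, `pav`, `pangenome`, `pca`, `tree`, `gwas`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if ("association" %in% config$stages && is.null(config$phenotypes))
    stop("association stage enabled but no phenotype table configured")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  genes <- parse_gff3(config$annotation)
  if (!is.null(config$allowed_chromosomes))
    genes <- filter_chromosomes(genes, config$allowed_chromosomes)
  if (length(genes) == 0L) stop("no genes left after chromosome filtering")
  gt <- gene_table(genes)
  data.table::fwrite(gt, file.path(out, "genes.tsv"), sep = "\t")
  counts$genes <- nrow(gt)

  bgs <- sort(list.files(config$depth_dir, pattern = "\\.bedgraph$",
                         full.names = TRUE))
  if (length(bgs) == 0L) stop("no .bedgraph files in ", config$depth_dir)
  tracks <- lapply(bgs, function(p)
    read_bedgraph(p, sample_id = sub("\\.bedgraph$", "", basename(p))))
  counts$samples <- length(tracks)

  params <- pav_params(config$min_cov, config$lost_cutoff)
  pav <- build_pav_matrix(genes, tracks, params)
  write_pav_matrix(pav, out, prefix = "pav")
  results <- list(genes = genes, pav = pav)

  if ("pangenome" %in% config$stages) {
    pg <- pangenome_summary(pav)
    cls_df <- data.frame(class = PANGENOME_CLASSES,
                         count = as.integer(pg$class_counts),
                         pct = as.numeric(pg$class_pct))
    data.table::fwrite(cls_df, file.path(out, "pangenome_classes.tsv"), sep = "\t")
    data.table::fwrite(pg$per_sample, file.path(out, "pangenome_per_sample.tsv"),
                       sep = "\t")
    data.table::fwrite(per_chromosome_distribution(pav, genes),
                       file.path(out, "pangenome_per_chromosome.tsv"), sep = "\t")
    data.table::fwrite(dispensable_list(pav, genes),
                       file.path(out, "dispensable_genes.tsv"), sep = "\t")
    counts$dispensable <- pg$n_variable
    results$pangenome <- pg
  }

  if ("popgen" %in% config$stages) {
    d <- pav_distance(pav)
    write_tsv_matrix(d, file.path(out, "pav_distance.tsv"), "sample_id")
    tree <- neighbor_joining(d)
    ape::write.tree(tree, file.path(out, "nj_tree.nwk"))
    pca <- pav_pca(pav, k = config$pca_k)
    write_tsv_matrix(pca$scores, file.path(out, "pca_scores.tsv"), "sample_id")
    data.table::fwrite(data.frame(component = seq_along(pca$var_explained),
                                  var_explained = pca$var_explained),
                       file.path(out, "pca_variance.tsv"), sep = "\t")
    results$tree <- tree
    results$pca <- pca
  }

  if ("association" %in% config$stages) {
    tt <- trait_table(config$phenotypes)
    gwas <- run_gwas(pav, tt, genes = genes,
                     maf_threshold = config$maf_threshold,
                     chrom_filter = config$allowed_chromosomes)
    data.table::fwrite(gwas, file.path(out, "gwas_full.tsv"), sep = "\t")
    data.table::fwrite(gwas[gwas$tier != "none", ],
                       file.path(out, "gwas_tiered.tsv"), sep = "\t")
    counts$gwas_tests <- nrow(gwas)
    counts$gwas_loci <- attr(gwas, "n_loci")
    results$gwas <- gwas
  }

  files <- setdiff(list.files(out, recursive = TRUE, full.names = TRUE),
                   file.path(out, "manifest.json"))
  cfg <- unclass(config)
  manifest <- list(
    package = "pavpipe",
    version = as.character(utils::packageVersion("pavpipe")),
    config = cfg,
    config_md5 = digest_config(cfg),
    stage_counts = counts,
    files = data.frame(path = sub(paste0("^", out, "/?"), "", files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

digest_config <- function(cfg) {
  # hash the analytic configuration; the output location is not part of it
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
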