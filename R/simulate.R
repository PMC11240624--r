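#' Design of a synthetic PAV study
#'
#' Describes the population and data shape the generator emulates: a
#' single-breed cohort of ~150 animals sequenced at ~20x, a few hundred
#' annotated genes on several autosomes, class quotas mirroring a strongly
#' core-dominated pangenome, and quantitative phenotypes with optional
#' planted additive PAV effects. All randomness flows from `seed`.
#'
#' @param n_samples Number of animals (default 150).
#' @param n_chromosomes Number of autosomes (default 5).
#' @param genes_per_chromosome Genes per chromosome (default 100).
#' @param class_quotas Named counts of `core`, `softcore`, `shell`,
#'   `cloud` genes; must sum to the total gene count. Defaults mirror a
#'   ~94% core pangenome at toy scale.
#' @param absent_in_all How many cloud genes are absent from every sample.
#' @param mean_depth Poisson mean per exonic base of a present gene
#'   (x-fold, default 20).
#' @param contamination_rate Probability that a base of an absent gene
#'   still receives a single stray read (default 0).
#' @param n_traits Number of phenotypes (default 5).
#' @param causal data.frame with columns `trait`, `frequency`, `beta`:
#'   each row plants one causal gene at the given presence frequency with
#'   additive effect `beta` (in residual-s.d. units) on the trait. Causal
#'   genes are drawn from the shell quota.
#' @param residual_sd Residual standard deviation of the phenotypes.
#' @param reliability_range Range of per-cell reliabilities, default
#'   `c(0.5, 0.99)`.
#' @param seed Integer seed driving every stage.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_samples = 150L, n_chromosomes = 5L,
                       genes_per_chromosome = 100L,
                       class_quotas = c(core = 469L, softcore = 16L,
                                        shell = 9L, cloud = 6L),
                       absent_in_all = 3L, mean_depth = 20,
                       contamination_rate = 0, n_traits = 5L,
                       causal = NULL, residual_sd = 1,
                       reliability_range = c(0.5, 0.99), seed = 1L) {
  n_genes <- n_chromosomes * genes_per_chromosome
  stopifnot(all(PANGENOME_CLASSES %in% names(class_quotas)),
            n_samples >= 2L, mean_depth >= 0, residual_sd > 0,
            contamination_rate >= 0, contamination_rate <= 1)
  if (sum(class_quotas) != n_genes)
    stop("class quotas sum to ", sum(class_quotas), " but the design has ",
         n_genes, " genes")
  if (absent_in_all > class_quotas[["cloud"]])
    stop("absent_in_all exceeds the cloud quota")
  if (class_quotas[["softcore"]] > 0L && softcore_min(n_samples) > n_samples - 1L)
    stop("softcore bin is empty at n_samples = ", n_samples)
  if (!is.null(causal)) {
    stopifnot(all(c("trait", "frequency", "beta") %in% names(causal)),
              all(is.finite(causal$beta)))
    if (nrow(causal) > class_quotas[["shell"]])
      stop("more causal genes requested than shell quota")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 n_genes = as.integer(n_genes),
                 class_quotas = class_quotas, absent_in_all = as.integer(absent_in_all),
                 mean_depth = mean_depth, contamination_rate = contamination_rate,
                 n_traits = as.integer(n_traits), causal = causal,
                 residual_sd = residual_sd, reliability_range = reliability_range,
                 seed = as.integer(seed)),
            class = "sim_design")
}

# smallest presence count whose frequency falls in [0.95, 1); the 1e-9
# nudge keeps exact multiples (0.95 * n integer) inside the closed edge
softcore_min <- function(n) as.integer(ceiling(0.95 * n - 1e-9))
shell_min <- function(n) as.integer(ceiling(0.05 * n - 1e-9))

# sample() semantics are unsafe for length-1 x; draw by index instead
resample <- function(x, size) x[sample.int(length(x), size, replace = TRUE)]

#' Simulate a gene annotation
#'
#' Lays non-overlapping genes along each chromosome with 1-3 transcripts
#' of 1-5 exons each. The first gene of every chromosome carries a planted
#' decoy: an alternative transcript with a wider genomic span but a
#' smaller exonic sum, so longest-transcript selection by exonic length is
#' exercised. Gene categories (protein_coding, uncharacterized, tRNA,
#' miRNA) are sampled for dispensable-list reporting.
#'
#' @param design A [sim_design()].
#' @param gff3_path Optional path; when given the annotation is also
#'   written as GFF3.
#' @return A named list of [gene_model()]s (with `chrom_lengths` attached
#'   as an attribute).
#' @export
simulate_annotation <- function(design, gff3_path = NULL) {
  set.seed(design$seed + 1L)
  genes <- list()
  chrom_lengths <- integer(design$n_chromosomes)
  gidx <- 0L
  for (ci in seq_len(design$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    cursor <- 0L
    for (gi in seq_len(design$genes_per_chromosome)) {
      gidx <- gidx + 1L
      gene_id <- sprintf("g%04d", gidx)
      cursor <- cursor + sample(200:500, 1L)  # intergenic gap
      if (gi == 1L) {
        # decoy: tA spans wide with 2 x 50 bp exons; tB is compact, 150 bp
        tA <- list(transcript_id = paste0(gene_id, ".tA"),
                   exons = data.frame(start = cursor + c(0L, 950L),
                                      end = cursor + c(50L, 1000L)))
        tB <- list(transcript_id = paste0(gene_id, ".tB"),
                   exons = data.frame(start = cursor, end = cursor + 150L))
        txs <- list(tA, tB)
        span <- 1000L
      } else {
        n_tx <- sample(1:3, 1L)
        txs <- vector("list", n_tx)
        span <- 0L
        for (ti in seq_len(n_tx)) {
          n_ex <- sample(1:5, 1L)
          ex_len <- sample(30:120, n_ex, replace = TRUE)
          gaps <- if (n_ex > 1L) sample(20:200, n_ex - 1L, replace = TRUE) else integer()
          starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + gaps))
          txs[[ti]] <- list(transcript_id = sprintf("%s.t%d", gene_id, ti),
                            exons = data.frame(start = starts,
                                               end = starts + ex_len))
          span <- max(span, max(starts + ex_len) - cursor)
        }
      }
      cat_lab <- sample(c("protein_coding", "uncharacterized", "tRNA", "miRNA"),
                        1L, prob = c(0.55, 0.30, 0.10, 0.05))
      genes[[gene_id]] <- gene_model(gene_id, chrom,
                                     strand = sample(c("+", "-"), 1L),
                                     transcripts = txs, category = cat_lab)
      cursor <- cursor + span
    }
    chrom_lengths[ci] <- cursor + 500L
  }
  names(chrom_lengths) <- paste0("chr", seq_len(design$n_chromosomes))
  attr(genes, "chrom_lengths") <- chrom_lengths
  if (!is.null(gff3_path)) write_gff3(genes, gff3_path)
  genes
}

#' Write gene models as GFF3
#'
#' Inverse of [parse_gff3()]: emits gene / mRNA / exon features with
#' ID/Parent links, converting internal 0-based half-open intervals back
#' to GFF3's 1-based inclusive coordinates.
#'
#' @param genes List of [gene_model()]s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    ex_all <- do.call(rbind, lapply(g$transcripts, `[[`, "exons"))
    gstart <- min(ex_all$start); gend <- max(ex_all$end)
    lines <- c(lines, sprintf(
      "%s\tpavpipe\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
      g$chrom, gstart + 1L, gend, g$strand, g$gene_id, g$category))
    for (tx in g$transcripts) {
      lines <- c(lines, sprintf(
        "%s\tpavpipe\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom, min(tx$exons$start) + 1L, max(tx$exons$end), g$strand,
        tx$transcript_id, g$gene_id))
      for (i in seq_len(nrow(tx$exons)))
        lines <- c(lines, sprintf(
          "%s\tpavpipe\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          g$chrom, tx$exons$start[i] + 1L, tx$exons$end[i], g$strand,
          tx$transcript_id, i, tx$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate the ground-truth presence structure
#'
#' Assigns every gene a pangenome class according to the design quotas,
#' draws a presence count inside that class's frequency bin, and scatters
#' the carriers uniformly across samples. Causal genes (if any) are taken
#' from the shell quota and given their exact requested presence count.
#'
#' @param design A [sim_design()].
#' @param genes Annotation from [simulate_annotation()] (gene ids/order).
#' @return A list: `$truth` (a `pav_matrix` of planted presence),
#'   `$class` (factor of assigned classes per gene), `$causal` (the design
#'   causal table with a `gene_id` column attached, or NULL).
#' @export
simulate_presence <- function(design, genes) {
  set.seed(design$seed + 2L)
  n <- design$n_samples
  gene_ids <- names(genes)
  q <- design$class_quotas
  cls <- sample(rep(factor(PANGENOME_CLASSES, levels = PANGENOME_CLASSES), q))
  names(cls) <- gene_ids

  sc_min <- softcore_min(n); sh_min <- shell_min(n)
  counts <- integer(length(gene_ids))
  counts[cls == "core"] <- n
  counts[cls == "softcore"] <- resample(sc_min:(n - 1L), sum(cls == "softcore"))
  counts[cls == "shell"] <- resample(sh_min:(sc_min - 1L), sum(cls == "shell"))
  cloud_idx <- which(cls == "cloud")
  zero_idx <- cloud_idx[seq_len(design$absent_in_all)]
  draw_idx <- setdiff(cloud_idx, zero_idx)
  if (sh_min - 1L >= 1L)
    counts[draw_idx] <- resample(1:(sh_min - 1L), length(draw_idx))
  counts[zero_idx] <- 0L

  causal <- design$causal
  if (!is.null(causal)) {
    shell_pool <- sample(which(cls == "shell"))
    causal$gene_id <- gene_ids[shell_pool[seq_len(nrow(causal))]]
    counts[shell_pool[seq_len(nrow(causal))]] <- as.integer(round(causal$frequency * n))
  }

  pres <- matrix(0L, length(gene_ids), n,
                 dimnames = list(gene_ids, sprintf("s%03d", seq_len(n))))
  for (i in seq_along(gene_ids))
    if (counts[i] > 0L) pres[i, sample.int(n, counts[i])] <- 1L
  list(truth = new_pav_matrix(pres), class = cls, causal = causal)
}

#' Simulate per-sample sequencing depth
#'
#' For each sample, exonic bases of genes the sample carries receive
#' independent Poisson(`mean_depth`) depth; exonic bases of absent genes
#' are zero apart from optional Bernoulli stray single reads
#' (`contamination_rate`); intergenic bases are zero. Depth is placed over
#' the union of all exons of all transcripts of a gene, so any
#' transcript-level coverage rule sees consistent data.
#'
#' @param design A [sim_design()].
#' @param genes Annotation from [simulate_annotation()].
#' @param truth Output of [simulate_presence()].
#' @param bedgraph_dir Optional directory; when given, one
#'   `<sample>.bedgraph` per sample (non-zero runs only) is written.
#' @return A list of [depth_track()]s, one per sample.
#' @export
simulate_depth <- function(design, genes, truth, bedgraph_dir = NULL) {
  set.seed(design$seed + 3L)
  chrom_lengths <- attr(genes, "chrom_lengths")
  pres <- truth$truth$presence
  # gene-level exon union (all transcripts), grouped by chromosome
  union_by_chrom <- list()
  for (g in genes) {
    ex <- merge_intervals(do.call(rbind, lapply(g$transcripts, `[[`, "exons")))
    ex$gene_id <- g$gene_id
    union_by_chrom[[g$chrom]] <- rbind(union_by_chrom[[g$chrom]], ex)
  }
  if (!is.null(bedgraph_dir))
    dir.create(bedgraph_dir, recursive = TRUE, showWarnings = FALSE)
  tracks <- vector("list", design$n_samples)
  for (s in seq_len(design$n_samples)) {
    sid <- colnames(pres)[s]
    runs <- vector("list", length(chrom_lengths))
    names(runs) <- names(chrom_lengths)
    for (chrom in names(chrom_lengths)) {
      vec <- integer(chrom_lengths[[chrom]])
      ub <- union_by_chrom[[chrom]]
      for (i in seq_len(nrow(ub))) {
        pos <- (ub$start[i] + 1L):ub$end[i]
        if (pres[ub$gene_id[i], s] == 1L) {
          vec[pos] <- stats::rpois(length(pos), design$mean_depth)
        } else if (design$contamination_rate > 0) {
          vec[pos] <- stats::rbinom(length(pos), 1L, design$contamination_rate)
        }
      }
      runs[[chrom]] <- S4Vectors::Rle(vec)
    }
    tracks[[s]] <- structure(list(sample_id = sid, runs = runs),
                             class = "depth_track")
    if (!is.null(bedgraph_dir))
      write_bedgraph(tracks[[s]], file.path(bedgraph_dir, paste0(sid, ".bedgraph")))
  }
  tracks
}

#' Write a depth track as BedGraph (non-zero runs only)
#'
#' @param track A [depth_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$runs), function(chrom) {
    r <- track$runs[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)
    keep <- S4Vectors::runValue(r) > 0L
    data.table::data.table(chrom = chrom, start = starts[keep],
                           end = ends[keep], depth = S4Vectors::runValue(r)[keep])
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Write a depth track as a SAM of synthetic perfect reads
#'
#' Decomposes the per-base depth profile into horizontal "layers": each
#' maximal positive run at each depth level becomes one perfectly aligned
#' single-end read (all-M CIGAR, dummy sequence), so the read pileup
#' reproduces the track's depth base-for-base. Intended for small test
#' tracks to exercise BAM-based depth ingestion.
#'
#' @param track A [depth_track()].
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_depth_sam <- function(track, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              vapply(names(track$runs), function(chrom)
                sprintf("@SQ\tSN:%s\tLN:%d", chrom, length(track$runs[[chrom]])),
                character(1)))
  body <- character()
  rid <- 0L
  for (chrom in names(track$runs)) {
    depth <- as.integer(track$runs[[chrom]])
    while (any(depth > 0L)) {
      r <- rle(depth > 0L)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        rid <- rid + 1L
        len <- ends[k] - starts[k] + 1L
        body <- c(body, sprintf("r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                                rid, chrom, starts[k], len,
                                paste(rep("A", len), collapse = "")))
        depth[starts[k]:ends[k]] <- depth[starts[k]:ends[k]] - 1L
      }
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate phenotypes with planted PAV effects
#'
#' For each trait, the true de-regressed phenotype is
#' `dPTA = sum(beta * presence) + N(0, residual_sd^2)`; per-cell
#' reliabilities are uniform on the design range, and the emitted PTA is
#' `dPTA * reliability`, so [deregress()] inverts the construction
#' exactly.
#'
#' @param design A [sim_design()].
#' @param truth Output of [simulate_presence()].
#' @return A list: `$phenotypes` (long data.frame `sample_id`, `trait`,
#'   `pta`, `reliability`), `$dpta_truth` (samples x traits matrix).
#' @export
simulate_phenotypes <- function(design, truth) {
  set.seed(design$seed + 4L)
  n <- design$n_samples
  samples <- truth$truth$sample_ids
  trait_names <- sprintf("T%02d", seq_len(design$n_traits))
  dpta <- matrix(stats::rnorm(n * design$n_traits, 0, design$residual_sd),
                 n, design$n_traits, dimnames = list(samples, trait_names))
  if (!is.null(truth$causal)) {
    for (i in seq_len(nrow(truth$causal))) {
      tr <- truth$causal$trait[i]
      if (!tr %in% trait_names)
        stop("causal trait ", tr, " not among the design's traits")
      g <- truth$causal$gene_id[i]
      dpta[, tr] <- dpta[, tr] +
        truth$causal$beta[i] * design$residual_sd * truth$truth$presence[g, ]
    }
  }
  rel <- matrix(stats::runif(n * design$n_traits, design$reliability_range[1],
                             design$reliability_range[2]),
                n, design$n_traits, dimnames = dimnames(dpta))
  pta <- dpta * rel
  long <- data.frame(
    sample_id = rep(samples, times = design$n_traits),
    trait = rep(trait_names, each = n),
    pta = as.vector(pta),
    reliability = as.vector(rel))
  # the recorded truth is the de-regressed value implied by the emitted
  # (PTA, reliability) pair, so deregress() recovers it bit-for-bit
  list(phenotypes = long, dpta_truth = pta / rel)
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper: annotation, presence truth, depth tracks and
#' phenotypes from one design, optionally written to disk together with a
#' manifest (design echo, seed, file checksums).
#'
#' @param design A [sim_design()].
#' @param dir Optional output directory; when given, GFF3, per-sample
#'   BedGraphs, the phenotype TSV, the truth matrix and a manifest JSON
#'   are written beneath it.
#' @return A list with `genes`, `truth`, `class`, `causal`, `tracks`,
#'   `phenotypes`, `dpta_truth`, `design`.
#' @export
simulate_pav_study <- function(design = sim_design(), dir = NULL) {
  genes <- simulate_annotation(design,
    gff3_path = if (is.null(dir)) NULL else {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      file.path(dir, "annotation.gff3")
    })
  pr <- simulate_presence(design, genes)
  tracks <- simulate_depth(design, genes, pr,
    bedgraph_dir = if (is.null(dir)) NULL else file.path(dir, "depth"))
  ph <- simulate_phenotypes(design, pr)
  out <- list(genes = genes, truth = pr$truth, class = pr$class,
              causal = pr$causal, tracks = tracks,
              phenotypes = ph$phenotypes, dpta_truth = ph$dpta_truth,
              design = design)
  if (!is.null(dir)) {
    data.table::fwrite(ph$phenotypes, file.path(dir, "phenotypes.tsv"), sep = "\t")
    write_pav_matrix(pr$truth, dir, prefix = "truth")
    files <- list.files(dir, recursive = TRUE, full.names = TRUE)
    manifest <- list(seed = design$seed,
                     design = design[setdiff(names(design), "causal")],
                     causal = pr$causal,
                     files = data.frame(path = basename(files),
                                        md5 = unname(tools::md5sum(files))))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
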