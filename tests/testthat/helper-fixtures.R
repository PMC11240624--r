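# shared toy builders for the unit tests

toy_gene <- function(gene_id = "gA", chrom = "chr1", exons_by_tx,
                     strand = "+", category = "protein_coding") {
  txs <- lapply(seq_along(exons_by_tx), function(i)
    list(transcript_id = names(exons_by_tx)[i] %||% paste0(gene_id, ".t", i),
         exons = exons_by_tx[[i]]))
  gene_model(gene_id, chrom, strand, txs, category)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# depth track from explicit runs
toy_track <- function(sample_id, chrom, start, end, depth) {
  depth_track(sample_id, data.frame(chrom = chrom, start = start,
                                    end = end, depth = depth))
}

# uniform-depth track covering one interval per chromosome
flat_track <- function(sample_id, chroms, len, depth) {
  depth_track(sample_id, data.frame(chrom = chroms, start = 0L,
                                    end = len, depth = depth))
}

# small simulated study shared by several test files
small_design <- function(seed = 42, causal = NULL, ...) {
  sim_design(n_samples = 40, n_chromosomes = 2, genes_per_chromosome = 25,
             class_quotas = c(core = 38, softcore = 4, shell = 5, cloud = 3),
             absent_in_all = 1, n_traits = 2, seed = seed, causal = causal, ...)
}

# brute-force covered fraction: enumerate every exon-union base
brute_covered_fraction <- function(gene, track, min_cov) {
  bases <- unlist(lapply(seq_len(nrow(gene$exon_union)), function(i)
    gene$exon_union$start[i]:(gene$exon_union$end[i] - 1L)))
  d <- vapply(bases, function(b)
    query_depth(track, gene$chrom, b, b + 1L)[1L], integer(1))
  mean(d >= min_cov)
}

# one-sided hypergeometric tail for a 2x2 overrepresentation table
brute_fisher_p <- function(a, q, s, n) {
  k <- a:min(q, s)
  sum(stats::dhyper(k, s, n - s, q))
}
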