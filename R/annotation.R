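#' Merge genomic intervals into a disjoint union
#'
#' Merges a set of half-open, 0-based intervals on a single chromosome into
#' sorted, non-overlapping, non-adjacent intervals. Touching intervals
#' (e.g. `[0,10)` and `[10,20)`) are merged, so the total length of the
#' result equals the number of distinct covered bases.
#'
#' @param intervals A data.frame with integer columns `start` and `end`
#'   (0-based half-open, `start < end`), optionally a `chrom` column which
#'   must then be constant.
#' @return A data.frame with columns `start`, `end`, sorted by `start`.
#' @examples
#' merge_intervals(data.frame(start = c(0L, 5L), end = c(10L, 15L)))
#' @export
merge_intervals <- function(intervals) {
  if (!is.data.frame(intervals) || !all(c("start", "end") %in% names(intervals)))
    stop("'intervals' must be a data.frame with 'start' and 'end' columns")
  if ("chrom" %in% names(intervals) && length(unique(intervals$chrom)) > 1L)
    stop("merge_intervals: intervals span multiple chromosomes: ",
         paste(unique(intervals$chrom), collapse = ", "))
  if (nrow(intervals) == 0L)
    return(data.frame(start = integer(), end = integer()))
  if (any(intervals$start >= intervals$end))
    stop("merge_intervals: empty or inverted interval (start >= end)")
  ir <- IRanges::reduce(IRanges::IRanges(start = intervals$start + 1L,
                                         end = intervals$end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

interval_length <- function(intervals) {
  if (nrow(intervals) == 0L) return(0L)
  sum(intervals$end - intervals$start)
}

new_transcript_model <- function(transcript_id, exons) {
  merged <- merge_intervals(exons[, c("start", "end"), drop = FALSE])
  structure(list(transcript_id = transcript_id,
                 exons = exons[order(exons$start), c("start", "end"), drop = FALSE],
                 exonic_length = interval_length(merged)),
            class = "transcript_model")
}

#' Construct a gene model
#'
#' A gene model holds a gene's transcripts (each a set of exon intervals in
#' 0-based half-open coordinates), the selected longest transcript and the
#' merged exon union over which presence/absence coverage is later assessed.
#' Strand is carried for reporting but plays no role in coverage.
#'
#' @param gene_id Gene identifier (unique within an annotation).
#' @param chrom Chromosome name.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param transcripts Named or unnamed list; each element a list with
#'   `transcript_id` and `exons` (data.frame `start`,`end`, 0-based half-open).
#' @param category Free-text biotype label (e.g. `protein_coding`, `tRNA`).
#' @return An object of class `gene_model` with the longest transcript
#'   selected (see [select_longest()]).
#' @export
gene_model <- function(gene_id, chrom, strand = ".", transcripts, category = NA_character_) {
  stopifnot(length(gene_id) == 1L, nzchar(chrom), length(transcripts) >= 1L)
  txs <- lapply(transcripts, function(t) {
    if (inherits(t, "transcript_model")) t
    else new_transcript_model(t$transcript_id, t$exons)
  })
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  g <- structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                      strand = strand, transcripts = txs,
                      category = as.character(category),
                      longest = NULL, exon_union = NULL),
                 class = "gene_model")
  select_longest(g)
}

#' Select the longest transcript of a gene
#'
#' "Longest" is measured as total exonic length (the number of distinct
#' exon bases after merging), not genomic span: downstream coverage is
#' assessed over exons, so exonic length is the relevant size. Ties are
#' broken by the lexicographically smallest transcript id, which makes the
#' selection deterministic and invariant to transcript order.
#'
#' @param gene A `gene_model`.
#' @return The same `gene_model` with `$longest` (a transcript model) and
#'   `$exon_union` (merged exon intervals of the selected transcript) set.
#' @export
select_longest <- function(gene) {
  stopifnot(inherits(gene, "gene_model"), length(gene$transcripts) >= 1L)
  len <- vapply(gene$transcripts, `[[`, integer(1), "exonic_length")
  ids <- vapply(gene$transcripts, `[[`, character(1), "transcript_id")
  best <- which(len == max(len))
  pick <- best[order(ids[best])][1L]
  gene$longest <- gene$transcripts[[pick]]
  gene$exon_union <- merge_intervals(gene$longest$exons)
  if (interval_length(gene$exon_union) <= 0L)
    stop("gene ", gene$gene_id, ": selected transcript has zero exonic length")
  gene
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s(%s) %d transcript(s); longest %s (%d exonic bp)\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts),
              x$longest$transcript_id, x$longest$exonic_length))
  invisible(x)
}

#' Parse a GFF3 gene annotation into gene models
#'
#' Reads GFF3 (`gene` / `mRNA` or `transcript` / `exon` features linked by
#' `ID`/`Parent`) and returns one [gene_model()] per gene. GFF3's 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention at this boundary. Genes with no exon-bearing transcript are
#' excluded with a warning rather than fabricated from the gene span.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of `gene_model` objects (names = gene ids), each
#'   with its longest transcript already selected.
#' @export
parse_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  id <- as.character(meta$ID)
  parent <- vapply(as.list(meta$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  # internal 0-based half-open: GFF3 [start,end] 1-based -> [start-1, end)
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  biotype <- if ("biotype" %in% names(meta)) as.character(meta$biotype)
             else if ("gene_biotype" %in% names(meta)) as.character(meta$gene_biotype)
             else rep(NA_character_, length(gr))

  tx_gene <- parent[is_tx]
  names(tx_gene) <- id[is_tx]
  exon_parent <- parent[is_exon]
  unknown <- setdiff(unique(exon_parent), names(tx_gene))
  if (length(unknown))
    stop("exon features with unknown Parent transcript(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))

  exon_df <- data.frame(tx = exon_parent, start = start0[is_exon],
                        end = end0[is_exon], stringsAsFactors = FALSE)
  exons_by_tx <- split(exon_df[, c("start", "end")], exon_df$tx)

  genes <- list()
  dropped <- character()
  for (gi in which(is_gene)) {
    gid <- id[gi]
    tx_ids <- names(tx_gene)[tx_gene == gid]
    tx_ids <- tx_ids[tx_ids %in% names(exons_by_tx)]
    if (length(tx_ids) == 0L) { dropped <- c(dropped, gid); next }
    txs <- lapply(tx_ids, function(t)
      new_transcript_model(t, exons_by_tx[[t]]))
    genes[[gid]] <- gene_model(gid, chrom[gi], strand[gi], txs,
                               category = biotype[gi])
  }
  if (length(dropped))
    warning(length(dropped), " gene(s) without exon-bearing transcripts excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  genes
}

#' Keep only genes on an allowed set of chromosomes
#'
#' Used to restrict an annotation to autosomes before PAV analysis.
#'
#' @param genes List of `gene_model`s.
#' @param allowed Character vector of chromosome names to retain.
#' @return The filtered list, original order preserved.
#' @export
filter_chromosomes <- function(genes, allowed) {
  genes[vapply(genes, function(g) g$chrom %in% allowed, logical(1))]
}

#' Tabulate gene models
#'
#' @param genes List of `gene_model`s.
#' @return A data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start` (0-based start of the exon union), `longest_transcript_id`,
#'   `exonic_length`, `category`.
#' @export
gene_table <- function(genes) {
  data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    start = vapply(genes, function(g) g$exon_union$start[1L], integer(1)),
    longest_transcript_id = vapply(genes, function(g) g$longest$transcript_id, ""),
    exonic_length = vapply(genes, function(g) g$longest$exonic_length, integer(1)),
    category = vapply(genes, `[[`, "", "category"),
    row.names = NULL, stringsAsFactors = FALSE)
}
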