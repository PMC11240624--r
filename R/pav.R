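#' PAV-calling parameters
#'
#' `min_cov` is the per-base depth a position must reach to count as
#' covered; `lost_cutoff` is the covered-fraction threshold below or at
#' which a gene is called absent. The defaults (5 reads, 0.2) are the
#' standard settings for breadth-of-coverage gene-loss calling from
#' ~20x short-read data.
#'
#' @param min_cov Integer depth threshold (>= 1); a base is covered when
#'   its depth is `>= min_cov`.
#' @param lost_cutoff Fraction in (0,1); a gene is present when strictly
#'   more than this fraction of its exon-union bases is covered.
#' @return An object of class `pav_params`.
#' @export
pav_params <- function(min_cov = 5L, lost_cutoff = 0.2) {
  stopifnot(min_cov >= 1L, lost_cutoff > 0, lost_cutoff < 1)
  structure(list(min_cov = as.integer(min_cov), lost_cutoff = lost_cutoff),
            class = "pav_params")
}

query_depth_quiet <- function(track, chrom, start, end) {
  rle <- track$runs[[chrom]]
  n <- end - start
  if (is.null(rle) || start >= length(rle)) return(integer(n))
  hi <- min(end, length(rle))
  out <- as.integer(S4Vectors::window(rle, start + 1L, hi))
  if (hi < end) out <- c(out, integer(end - hi))
  out
}

#' Covered fraction of a gene's exon union
#'
#' The breadth of coverage used for presence calling: the fraction of the
#' gene's exon-union bases (longest transcript only) whose depth reaches
#' `min_cov`. An absent chromosome contributes depth 0.
#'
#' @param gene A [gene_model()].
#' @param track A [depth_track()].
#' @param min_cov Integer depth threshold.
#' @return A fraction in `[0, 1]`.
#' @export
covered_fraction <- function(gene, track, min_cov = 5L) {
  u <- gene$exon_union
  total <- interval_length(u)
  if (total <= 0L) stop("gene ", gene$gene_id, " has an empty exon union")
  covered <- 0L
  for (i in seq_len(nrow(u))) {
    d <- query_depth_quiet(track, gene$chrom, u$start[i], u$end[i])
    covered <- covered + sum(d >= min_cov)
  }
  covered / total
}

#' Presence call from a covered fraction
#'
#' Present if and only if the covered fraction strictly exceeds
#' `lost_cutoff` ("more than 20% coverage"): a fraction exactly at the
#' cutoff is called absent.
#'
#' @param fraction Covered fraction in `[0, 1]` (vectorised).
#' @param params A [pav_params()].
#' @return Integer 0/1 vector, 1 = present.
#' @export
call_presence <- function(fraction, params = pav_params()) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  as.integer(fraction > params$lost_cutoff)
}

#' Build the genes x samples PAV matrix
#'
#' Applies [covered_fraction()] and [call_presence()] to every
#' (gene, sample) pair and assembles the binary presence matrix together
#' with the underlying covered fractions (kept so borderline calls remain
#' inspectable) and per-gene presence frequencies.
#'
#' @param genes List of [gene_model()]s.
#' @param tracks List of [depth_track()]s with unique sample ids.
#' @param params A [pav_params()].
#' @return An object of class `pav_matrix`: `$presence` (integer 0/1 matrix,
#'   genes x samples), `$fractions` (same shape), `$gene_ids`, `$sample_ids`,
#'   `$presence_count`, `$presence_frequency`, `$params`.
#' @export
build_pav_matrix <- function(genes, tracks, params = pav_params()) {
  stopifnot(length(genes) >= 1L, length(tracks) >= 1L)
  sample_ids <- unname(vapply(tracks, `[[`, "", "sample_id"))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_id: ", sample_ids[duplicated(sample_ids)][1L])
  gene_ids <- unname(vapply(genes, `[[`, "", "gene_id"))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_id: ", gene_ids[duplicated(gene_ids)][1L])
  frac <- matrix(NA_real_, nrow = length(genes), ncol = length(tracks),
                 dimnames = list(gene_ids, sample_ids))
  # per chromosome: 1-based base positions of every gene's exon union plus
  # the owning gene, so each sample's depth is decoded only once per chrom
  chroms <- unique(vapply(genes, `[[`, "", "chrom"))
  layout <- lapply(chroms, function(ch) {
    on_ch <- which(vapply(genes, function(g) g$chrom == ch, logical(1)))
    pos <- lapply(on_ch, function(i) {
      u <- genes[[i]]$exon_union
      unlist(lapply(seq_len(nrow(u)), function(r) (u$start[r] + 1L):u$end[r]))
    })
    list(gene_idx = rep(on_ch, lengths(pos)), pos = unlist(pos),
         len = lengths(pos))
  })
  names(layout) <- chroms
  union_len <- integer(length(genes))
  for (lay in layout) union_len[unique(lay$gene_idx)] <- lay$len
  if (any(union_len <= 0L))
    stop("gene ", gene_ids[which(union_len <= 0L)[1L]], " has an empty exon union")
  for (s in seq_along(tracks)) {
    covered <- numeric(length(genes))
    for (ch in chroms) {
      lay <- layout[[ch]]
      rle <- tracks[[s]]$runs[[ch]]
      if (is.null(rle)) next
      v <- as.integer(rle)
      d <- ifelse(lay$pos <= length(v), v[pmin(lay$pos, length(v))], 0L)
      hit <- rowsum(as.integer(d >= params$min_cov), lay$gene_idx)
      covered[as.integer(rownames(hit))] <- hit[, 1L]
    }
    frac[, s] <- covered / union_len
  }
  pres <- matrix(call_presence(frac, params), nrow = nrow(frac),
                 dimnames = dimnames(frac))
  new_pav_matrix(pres, fractions = frac, params = params)
}

#' Assemble a `pav_matrix` from a binary presence matrix
#'
#' Lower-level constructor used by the caller, the simulator (truth
#' matrices) and any external presence matrix a user brings.
#'
#' @param presence Integer/logical matrix, genes in rows, samples in
#'   columns, dimnames required.
#' @param fractions Optional matrix of covered fractions, same shape.
#' @param params Optional [pav_params()] used to produce the calls.
#' @return A `pav_matrix`.
#' @export
new_pav_matrix <- function(presence, fractions = NULL, params = NULL) {
  stopifnot(is.matrix(presence), !is.null(rownames(presence)),
            !is.null(colnames(presence)),
            all(presence %in% c(0L, 1L)))
  if (anyDuplicated(rownames(presence)) || anyDuplicated(colnames(presence)))
    stop("gene and sample labels must be unique")
  storage.mode(presence) <- "integer"
  cnt <- rowSums(presence)
  structure(list(presence = presence, fractions = fractions,
                 gene_ids = rownames(presence), sample_ids = colnames(presence),
                 presence_count = cnt,
                 presence_frequency = cnt / ncol(presence),
                 params = params),
            class = "pav_matrix")
}

#' @export
print.pav_matrix <- function(x, ...) {
  cat(sprintf("<pav_matrix> %d genes x %d samples; mean presence %.4f\n",
              nrow(x$presence), ncol(x$presence), mean(x$presence)))
  invisible(x)
}

#' Write a PAV matrix (and covered fractions) to TSV
#'
#' @param pav A `pav_matrix`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_pav_matrix <- function(pav, dir, prefix = "pav") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_matrix.tsv", "_fractions.tsv")))
  write_tsv_matrix(pav$presence, paths[1L], "gene_id")
  if (!is.null(pav$fractions)) write_tsv_matrix(pav$fractions, paths[2L], "gene_id")
  else paths <- paths[1L]
  invisible(paths)
}

write_tsv_matrix <- function(m, path, id_col) {
  dt <- data.table::as.data.table(m, keep.rownames = id_col)
  data.table::fwrite(dt, path, sep = "\t")
}

#' Read a PAV matrix written by [write_pav_matrix()]
#'
#' @param path Path to the `*_matrix.tsv` file.
#' @return A `pav_matrix` (without fractions or params).
#' @export
read_pav_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1L]]
  new_pav_matrix(m)
}
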