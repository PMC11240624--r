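#' Construct a per-sample depth track
#'
#' A depth track is a per-chromosome run-length encoding of per-base read
#' depth in 0-based half-open coordinates. Positions not covered by any run
#' (including whole chromosomes absent from the input) have depth 0: lack
#' of coverage is evidence of absence in the PAV caller, so no distinction
#' is made between "no data" and "depth zero".
#'
#' @param sample_id Sample identifier.
#' @param runs A data.frame with columns `chrom`, `start`, `end`, `depth`
#'   (0-based half-open, depth a non-negative integer), sorted and
#'   non-overlapping within each chromosome.
#' @return An object of class `depth_track`: `$sample_id` plus `$runs`, a
#'   named list of [S4Vectors::Rle] depth vectors (one per chromosome,
#'   anchored at base 0).
#' @export
depth_track <- function(sample_id, runs) {
  stopifnot(is.data.frame(runs),
            all(c("chrom", "start", "end", "depth") %in% names(runs)))
  if (nrow(runs) && any(runs$depth < 0))
    stop("negative depth in runs for sample ", sample_id)
  if (nrow(runs) && any(runs$end <= runs$start))
    stop("empty or inverted depth run for sample ", sample_id)
  rles <- lapply(split(runs, runs$chrom), function(r) {
    r <- r[order(r$start), , drop = FALSE]
    if (any(r$start[-1L] < r$end[-nrow(r)]))
      stop("overlapping depth runs on ", r$chrom[1L], " for sample ", sample_id)
    gaps <- c(r$start[1L], r$start[-1L] - r$end[-nrow(r)])
    vals <- as.vector(rbind(0L, as.integer(r$depth)))
    lens <- as.vector(rbind(as.integer(gaps), as.integer(r$end - r$start)))
    keep <- lens > 0L
    S4Vectors::Rle(vals[keep], lens[keep])
  })
  structure(list(sample_id = as.character(sample_id), runs = rles),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> %s: %d chromosome(s), %.0f covered bases\n",
              x$sample_id, length(x$runs),
              sum(vapply(x$runs, function(r)
                sum(as.numeric(S4Vectors::runLength(r)[S4Vectors::runValue(r) > 0])),
                numeric(1)))))
  invisible(x)
}

#' Read a 4-column BedGraph depth file
#'
#' Accepts per-base depth output in BedGraph form (`chrom start end depth`,
#' 0-based half-open), e.g. as produced by mosdepth. Runs must be sorted
#' and non-overlapping within each chromosome; gaps are depth 0.
#'
#' @param path Path to the BedGraph file (plain text, no header).
#' @param sample_id Sample identifier to attach to the track.
#' @return A [depth_track()].
#' @export
read_bedgraph <- function(path, sample_id) {
  bg <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "depth"),
                          colClasses = list(character = 1, integer = 2:4))
  if (nrow(bg)) {
    if (any(bad <- bg$depth < 0))
      stop("negative depth at line ", which(bad)[1L], " of ", path)
    if (any(bad <- bg$end <= bg$start))
      stop("empty/inverted interval at line ", which(bad)[1L], " of ", path)
    prev_same <- c(FALSE, bg$chrom[-1L] == bg$chrom[-nrow(bg)])
    disorder <- prev_same & c(FALSE, bg$start[-1L] < bg$end[-nrow(bg)])
    if (any(disorder))
      stop("unsorted or overlapping intervals at line ", which(disorder)[1L],
           " of ", path)
  }
  depth_track(sample_id, as.data.frame(bg))
}

#' Per-base depth over a BAM file
#'
#' Optional adapter for coordinate-sorted, indexed BAM: counts aligned
#' reads overlapping each base, excluding unmapped and duplicate-flagged
#' reads, and returns the same run-length track [read_bedgraph()] produces.
#' No mapping-quality or proper-pair filter is applied; any such filtering
#' belongs to the upstream alignment workflow.
#'
#' @param path Path to an indexed BAM file.
#' @param sample_id Sample identifier.
#' @return A [depth_track()].
#' @export
depth_from_bam <- function(path, sample_id) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("depth_from_bam requires the Rsamtools and GenomicAlignments packages")
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path)))
    stop("BAM index (.bai) not found for ", path)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isDuplicate = FALSE)
  aln <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flags))
  if (length(aln) == 0L) {
    warning("no usable alignments in ", path, "; returning all-zero track")
    return(structure(list(sample_id = as.character(sample_id), runs = list()),
                     class = "depth_track"))
  }
  cov <- GenomicAlignments::coverage(aln)
  structure(list(sample_id = as.character(sample_id),
                 runs = as.list(cov)[vapply(cov, length, 1L) > 0]),
            class = "depth_track")
}

#' Query per-base depth over an interval
#'
#' @param track A [depth_track()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @return Integer vector of length `end - start`; positions beyond the
#'   recorded runs (or on an unknown chromosome, with a warning) are 0.
#' @export
query_depth <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "depth_track"), end > start, start >= 0)
  n <- end - start
  rle <- track$runs[[chrom]]
  if (is.null(rle)) {
    warning("chromosome ", chrom, " absent from depth track ",
            track$sample_id, "; depth 0 assumed")
    return(integer(n))
  }
  len <- length(rle)
  if (start >= len) return(integer(n))
  hi <- min(end, len)
  out <- as.integer(S4Vectors::window(rle, start + 1L, hi))
  if (hi < end) out <- c(out, integer(end - hi))
  out
}

#' Mean sequencing depth over a reference extent
#'
#' @param track A [depth_track()].
#' @param reference_extent Total reference length in bases (> 0) over which
#'   the fold-coverage is expressed.
#' @return A data.frame with `sample_id`, `mean_depth` (x-fold) and
#'   `reference_extent`.
#' @export
summarize_coverage <- function(track, reference_extent) {
  stopifnot(reference_extent > 0)
  mass <- sum(vapply(track$runs, function(r)
    sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r)),
    numeric(1)))
  data.frame(sample_id = track$sample_id,
             mean_depth = mass / reference_extent,
             reference_extent = reference_extent)
}
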