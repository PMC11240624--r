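PANGENOME_CLASSES <- c("core", "softcore", "shell", "cloud")

#' Round half away from zero
#'
#' Reported percentages use conventional half-up rounding (0.005 -> 0.01)
#' rather than R's round-half-even, so printed summaries match the usual
#' hand-computed values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify presence frequencies into pangenome classes
#'
#' Genes are binned by the fraction of samples carrying them: `core`
#' (frequency exactly 1), `softcore` (`[0.95, 1)`), `shell` (`[0.05, 0.95)`)
#' and `cloud` (`< 0.05`, including genes absent from every sample). Lower
#' bin edges are closed; the bins partition `[0, 1]`.
#'
#' @param f Numeric vector of presence frequencies in `[0, 1]`.
#' @return Factor with levels `core`, `softcore`, `shell`, `cloud`.
#' @export
classify_frequency <- function(f) {
  stopifnot(all(f >= 0 & f <= 1))
  out <- ifelse(f == 1, "core",
         ifelse(f >= 0.95, "softcore",
         ifelse(f >= 0.05, "shell", "cloud")))
  factor(out, levels = PANGENOME_CLASSES)
}

#' @rdname classify_frequency
#' @param presence_count Integer count of samples carrying the gene.
#' @param n_samples Total number of samples (>= 1).
#' @export
classify_gene <- function(presence_count, n_samples) {
  stopifnot(n_samples >= 1L,
            all(presence_count >= 0L & presence_count <= n_samples))
  classify_frequency(presence_count / n_samples)
}

#' Pangenome bookkeeping from class counts
#'
#' The arithmetic layer of [pangenome_summary()], exposed separately so
#' published count tables can be re-expressed without the underlying
#' matrix: percentages (2 decimals, half-up), the variable-gene total and
#' the present-in-any complement.
#'
#' @param class_counts Named numeric vector with entries `core`,
#'   `softcore`, `shell`, `cloud`.
#' @param mean_present Mean number of genes present per sample.
#' @param mean_absent Mean number of genes absent per sample.
#' @param absent_in_all Number of genes present in no sample.
#' @return A list with class counts/percentages, `n_variable`,
#'   `n_present_in_any`, `n_absent_in_all` and mean per-sample
#'   present/absent counts and percentages.
#' @export
pangenome_arithmetic <- function(class_counts, mean_present, mean_absent,
                                 absent_in_all) {
  stopifnot(all(PANGENOME_CLASSES %in% names(class_counts)))
  class_counts <- class_counts[PANGENOME_CLASSES]
  n_genes <- sum(class_counts)
  list(
    n_genes = n_genes,
    class_counts = class_counts,
    class_pct = round_half_up(100 * class_counts / n_genes, 2L),
    n_variable = unname(sum(class_counts[c("softcore", "shell", "cloud")])),
    n_present_in_any = n_genes - absent_in_all,
    n_absent_in_all = absent_in_all,
    mean_present = mean_present,
    mean_absent = mean_absent,
    mean_present_pct = round_half_up(100 * mean_present / n_genes, 2L),
    mean_absent_pct = round_half_up(100 * mean_absent / n_genes, 2L))
}

#' Summarise a PAV matrix as a pangenome
#'
#' Classifies every gene by presence frequency, counts the classes, and
#' reports per-sample and population-level present/absent statistics.
#'
#' @param pav A `pav_matrix`.
#' @return An object of class `pangenome_summary`: the fields of
#'   [pangenome_arithmetic()] plus `$gene_class` (factor per gene) and
#'   `$per_sample` (data.frame of per-sample present/absent counts and
#'   percentages).
#' @export
pangenome_summary <- function(pav) {
  stopifnot(inherits(pav, "pav_matrix"))
  n_samples <- ncol(pav$presence)
  cls <- classify_gene(pav$presence_count, n_samples)
  names(cls) <- pav$gene_ids
  counts <- table(cls)
  per_sample_present <- colSums(pav$presence)
  per_sample <- data.frame(
    sample_id = pav$sample_ids,
    n_present = per_sample_present,
    n_absent = nrow(pav$presence) - per_sample_present,
    pct_present = round_half_up(100 * per_sample_present / nrow(pav$presence), 2L),
    pct_absent = round_half_up(100 * (1 - per_sample_present / nrow(pav$presence)), 2L),
    row.names = NULL)
  out <- pangenome_arithmetic(
    stats::setNames(as.numeric(counts), names(counts)),
    mean_present = mean(per_sample$n_present),
    mean_absent = mean(per_sample$n_absent),
    absent_in_all = sum(pav$presence_count == 0L))
  out$n_samples <- n_samples
  out$gene_class <- cls
  out$per_sample <- per_sample
  structure(out, class = "pangenome_summary")
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat(sprintf("<pangenome_summary> %d genes, %d samples\n", x$n_genes, x$n_samples))
  for (cl in PANGENOME_CLASSES)
    cat(sprintf("  %-8s %6d (%.2f%%)\n", cl, x$class_counts[[cl]], x$class_pct[[cl]]))
  cat(sprintf("  variable %d; present in any %d; absent in all %d\n",
              x$n_variable, x$n_present_in_any, x$n_absent_in_all))
  cat(sprintf("  mean per sample: %.0f present (%.2f%%), %.0f absent (%.2f%%)\n",
              x$mean_present, x$mean_present_pct, x$mean_absent, x$mean_absent_pct))
  invisible(x)
}

#' Per-chromosome distribution of gene PAVs
#'
#' For each chromosome, counts genes present in at least one sample,
#' absent in at least one sample, present in all samples, and absent in
#' all samples.
#'
#' @param pav A `pav_matrix`.
#' @param genes List of [gene_model()]s covering every gene in the matrix.
#' @return A data.frame with one row per chromosome.
#' @export
per_chromosome_distribution <- function(pav, genes) {
  chrom <- vapply(genes, `[[`, "", "chrom")
  names(chrom) <- vapply(genes, `[[`, "", "gene_id")
  missing <- setdiff(pav$gene_ids, names(chrom))
  if (length(missing))
    stop("genes in matrix without annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  chrom <- chrom[pav$gene_ids]
  n <- ncol(pav$presence)
  dt <- data.table::data.table(chrom = chrom, count = pav$presence_count)
  out <- dt[, .(n_genes = .N,
                present_in_any = sum(count > 0L),
                absent_in_any = sum(count < n),
                present_in_all = sum(count == n),
                absent_in_all = sum(count == 0L)),
            by = chrom][order(chrom)]
  as.data.frame(out)
}

#' List dispensable (variable) genes
#'
#' Genes absent from at least one sample, with their presence frequency,
#' pangenome class, chromosome and annotation category; the attribute
#' `category_pct` gives the category composition of the list in percent.
#'
#' @param pav A `pav_matrix`.
#' @param genes List of [gene_model()]s.
#' @return A data.frame, one row per dispensable gene, sorted by
#'   increasing presence frequency then gene id.
#' @export
dispensable_list <- function(pav, genes) {
  gt <- gene_table(genes)
  rownames(gt) <- gt$gene_id
  n <- ncol(pav$presence)
  keep <- pav$presence_count < n
  ids <- pav$gene_ids[keep]
  out <- data.frame(
    gene_id = ids,
    chrom = gt[ids, "chrom"],
    category = gt[ids, "category"],
    presence_count = pav$presence_count[keep],
    presence_frequency = pav$presence_frequency[keep],
    class = classify_gene(pav$presence_count[keep], n),
    row.names = NULL)
  out <- out[order(out$presence_frequency, out$gene_id), ]
  rownames(out) <- NULL
  if (nrow(out))
    attr(out, "category_pct") <-
      round_half_up(100 * sort(table(out$category), decreasing = TRUE) / nrow(out), 2L)
  out
}
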