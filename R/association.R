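#' De-regress predicted transmitting abilities
#'
#' `dPTA = PTA / reliability`: dividing out the evaluation's reliability
#' removes shrinkage so the value can serve as a GWAS response. Missing
#' inputs yield missing outputs; non-positive reliabilities are an error.
#'
#' @param pta Numeric vector of PTA values (trait units).
#' @param reliability Numeric vector of reliabilities in `(0, 1]`.
#' @return Numeric vector of de-regressed PTAs.
#' @export
deregress <- function(pta, reliability) {
  if (any(reliability <= 0, na.rm = TRUE))
    stop("reliability must be > 0")
  if (any(reliability > 1, na.rm = TRUE))
    stop("reliability must be <= 1")
  pta / reliability
}

#' Build a samples x traits table of de-regressed PTAs
#'
#' Reads a long-format phenotype table (`sample_id`, `trait`, `pta`,
#' `reliability`) and returns wide matrices of PTA, reliability and dPTA.
#' Cells absent from the input are `NA`.
#'
#' @param pheno A data.frame or path to a TSV with columns `sample_id`,
#'   `trait`, `pta`, `reliability`.
#' @return An object of class `trait_table`: `$pta`, `$reliability`,
#'   `$dpta` (samples x traits matrices), `$sample_ids`, `$traits`.
#' @export
trait_table <- function(pheno) {
  if (is.character(pheno)) pheno <- data.table::fread(pheno, sep = "\t")
  pheno <- as.data.frame(pheno)
  stopifnot(all(c("sample_id", "trait", "pta", "reliability") %in% names(pheno)))
  samples <- unique(pheno$sample_id)
  traits <- unique(pheno$trait)
  shape <- list(samples, traits)
  mk <- function(col) {
    m <- matrix(NA_real_, length(samples), length(traits), dimnames = shape)
    m[cbind(match(pheno$sample_id, samples), match(pheno$trait, traits))] <- pheno[[col]]
    m
  }
  pta <- mk("pta"); rel <- mk("reliability")
  structure(list(pta = pta, reliability = rel, dpta = deregress(pta, rel),
                 sample_ids = samples, traits = traits),
            class = "trait_table")
}

#' Pairwise Pearson correlations between trait dPTAs
#'
#' Pearson r on pairwise-complete samples, with two-sided p-values from
#' the t transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom. Pairs with fewer than 3 complete observations, or a trait with
#' zero variance on the complete pairs, are left `NA` rather than
#' fabricated.
#'
#' @param traits A [trait_table()].
#' @return A list with symmetric matrices `$r`, `$p` and `$n` (complete
#'   pairs per cell).
#' @export
trait_correlations <- function(traits) {
  x <- traits$dpta
  k <- ncol(x)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(k)) for (j in i:k) {
    ok <- stats::complete.cases(x[, i], x[, j])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3L) next
    xi <- x[ok, i]; xj <- x[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    rij <- stats::cor(xi, xj)
    r[i, j] <- r[j, i] <- rij
    if (i == j) { p[i, j] <- 0; next }
    tt <- rij * sqrt((sum(ok) - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = sum(ok) - 2)
  }
  list(r = r, p = p, n = n)
}

#' Filter PAV markers by minor allele frequency
#'
#' For a binary PAV marker the minor allele frequency is
#' `min(f, 1 - f)` where `f` is the presence frequency among the samples
#' actually analysed. Markers are retained when MAF strictly exceeds the
#' threshold, which necessarily removes monomorphic markers.
#'
#' @param pav A `pav_matrix`.
#' @param threshold MAF threshold in `(0, 0.5)`; default 0.05.
#' @param samples_used Character vector of sample ids over which to
#'   compute frequencies (default: all samples in the matrix).
#' @return Character vector of retained gene ids.
#' @export
maf_filter <- function(pav, threshold = 0.05, samples_used = NULL) {
  stopifnot(threshold > 0, threshold < 0.5)
  if (is.null(samples_used)) samples_used <- pav$sample_ids
  missing <- setdiff(samples_used, pav$sample_ids)
  if (length(missing))
    stop("samples not in PAV matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  f <- rowMeans(pav$presence[, samples_used, drop = FALSE])
  maf <- pmin(f, 1 - f)
  pav$gene_ids[maf > threshold]
}

#' Single-marker general linear model association
#'
#' Ordinary least squares of the phenotype on a binary presence indicator
#' (intercept plus one regressor). The model F statistic on
#' `(1, n - 2)` degrees of freedom equals the squared pooled-variance
#' two-sample t statistic between carrier groups; the p-value is the upper
#' tail of the F distribution. Samples with missing phenotype are dropped
#' casewise.
#'
#' @param presence Integer 0/1 vector.
#' @param dpta Numeric phenotype vector of the same length (NAs allowed).
#' @return A list `F`, `p`, `n_used`; `NULL` if, after deletion, fewer
#'   than 3 samples remain or a genotype class is empty (no contrast).
#' @export
glm_assoc <- function(presence, dpta) {
  stopifnot(length(presence) == length(dpta), all(presence %in% 0:1))
  ok <- !is.na(dpta)
  g <- presence[ok]; y <- dpta[ok]
  n <- length(y)
  if (n < 3L || length(unique(g)) < 2L) return(NULL)
  n1 <- sum(g)
  sxx <- n1 * (1 - n1 / n)
  sxy <- sum(y[g == 1L]) - n1 * mean(y)
  syy <- sum((y - mean(y))^2)
  ssr <- sxy^2 / sxx
  sse <- syy - ssr
  f <- if (syy == 0) 0 else ssr / (sse / (n - 2L))
  list(F = f, p = stats::pf(f, 1, n - 2L, lower.tail = FALSE), n_used = n)
}

glm_assoc_matrix <- function(presence_mat, y) {
  # vectorised glm_assoc over marker rows, one phenotype (no NAs)
  n <- length(y)
  n1 <- rowSums(presence_mat)
  yc <- y - mean(y)
  sxx <- n1 * (1 - n1 / n)
  sxy <- as.vector(presence_mat %*% yc)
  syy <- sum(yc^2)
  ssr <- sxy^2 / sxx
  f <- ssr / ((syy - ssr) / (n - 2L))
  f[syy == 0] <- 0
  ok <- n1 > 0L & n1 < n
  f[!ok] <- NA_real_
  data.frame(F = f, p = stats::pf(f, 1, n - 2L, lower.tail = FALSE),
             n_used = n, usable = ok)
}

#' Bonferroni significance tier of a p-value
#'
#' Genome-wide `significant` when `p <= 0.05 / n_loci`, `suggestive` when
#' `0.05 / n_loci < p <= 0.1 / n_loci`, otherwise `none`. Comparisons are
#' inclusive at the thresholds.
#'
#' @param p Numeric vector of p-values.
#' @param n_loci Number of tested loci (>= 1).
#' @return Factor with levels `significant`, `suggestive`, `none`.
#' @export
bonferroni_tier <- function(p, n_loci) {
  stopifnot(n_loci >= 1L)
  out <- ifelse(p <= 0.05 / n_loci, "significant",
         ifelse(p <= 0.1 / n_loci, "suggestive", "none"))
  factor(out, levels = c("significant", "suggestive", "none"))
}

#' PAV-based genome-wide association across traits
#'
#' For every trait: restrict to samples with phenotypes, apply the MAF and
#' chromosome filters (MAF computed on the phenotyped subset), run
#' [glm_assoc()] marker by marker, and tier p-values with Bonferroni
#' thresholds where `n_loci` is the number of markers surviving the
#' filters (identical across traits).
#'
#' @param pav A `pav_matrix`.
#' @param traits A [trait_table()].
#' @param genes Optional list of [gene_model()]s used to attach chromosome
#'   and representative position (exon-union start) to each record and to
#'   apply `chrom_filter`.
#' @param maf_threshold MAF threshold, default 0.05.
#' @param chrom_filter Optional character vector of allowed chromosomes
#'   (e.g. autosomes); requires `genes`.
#' @return A data.frame of class `pav_gwas` with one row per
#'   (marker, trait): `gene_id`, `chrom`, `position`, `trait`, `n_used`,
#'   `F`, `p`, `tier`, sorted by p within trait; attribute `n_loci` holds
#'   the Bonferroni denominator.
#' @export
run_gwas <- function(pav, traits, genes = NULL, maf_threshold = 0.05,
                     chrom_filter = NULL) {
  shared <- intersect(pav$sample_ids, traits$sample_ids)
  if (length(shared) == 0L)
    stop("no samples shared between PAV matrix and phenotypes")
  gt <- NULL
  if (!is.null(genes)) {
    gt <- gene_table(genes)
    rownames(gt) <- gt$gene_id
  }
  markers <- maf_filter(pav, maf_threshold, samples_used = shared)
  if (!is.null(chrom_filter)) {
    if (is.null(gt)) stop("chrom_filter requires 'genes'")
    markers <- markers[gt[markers, "chrom"] %in% chrom_filter]
  }
  if (length(markers) == 0L)
    stop("no markers survive MAF/chromosome filtering")
  n_loci <- length(markers)
  pres <- pav$presence[markers, shared, drop = FALSE]

  res <- list()
  for (tr in traits$traits) {
    y <- traits$dpta[shared, tr]
    ok <- !is.na(y)
    if (sum(ok) < 3L) next
    st <- glm_assoc_matrix(pres[, ok, drop = FALSE], y[ok])
    keep <- st$usable
    if (!any(keep)) next
    res[[tr]] <- data.frame(
      gene_id = markers[keep],
      chrom = if (is.null(gt)) NA_character_ else gt[markers[keep], "chrom"],
      position = if (is.null(gt)) NA_integer_ else gt[markers[keep], "start"],
      trait = tr, n_used = st$n_used[keep], F = st$F[keep], p = st$p[keep],
      row.names = NULL)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable (marker, trait) pairs")
  out$tier <- bonferroni_tier(out$p, n_loci)
  out <- out[order(out$trait, out$p, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "n_loci") <- n_loci
  class(out) <- c("pav_gwas", "data.frame")
  out
}

#' Gene-set overrepresentation by Fisher's exact test
#'
#' One-sided (greater) Fisher's exact test of each annotation set against
#' a query gene list over a stated background, with Benjamini-Hochberg
#' adjustment across the sets tested. Annotation sets are intersected with
#' the background first.
#'
#' @param query Character vector of genes of interest (subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param annotation_sets Named list of character vectors.
#' @param fdr_cutoff Sets with adjusted FDR strictly below this value are
#'   flagged `enriched`; default 0.05.
#' @return A data.frame: `set`, `overlap`, `query_size`, `set_size`,
#'   `background_size`, `p`, `fdr`, `enriched`, sorted by p.
#' @export
fisher_enrichment <- function(query, background, annotation_sets,
                              fdr_cutoff = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  query <- unique(query)
  if (length(setdiff(query, background)))
    stop("query contains genes outside the background")
  rows <- lapply(names(annotation_sets), function(nm) {
    set <- intersect(unique(annotation_sets[[nm]]), background)
    a <- length(intersect(query, set))
    tab <- matrix(c(a, length(set) - a,
                    length(query) - a,
                    length(background) - length(set) - length(query) + a),
                  nrow = 2L)
    data.frame(set = nm, overlap = a, query_size = length(query),
               set_size = length(set), background_size = length(background),
               p = stats::fisher.test(tab, alternative = "greater")$p.value)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$fdr < fdr_cutoff
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
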