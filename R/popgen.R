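#' Pairwise PAV mismatch distance between samples
#'
#' The simple matching (Hamming) fraction: the proportion of genes whose
#' presence state differs between two samples. On binary vectors this is a
#' metric bounded by `[0, 1]`.
#'
#' @param pav A `pav_matrix`.
#' @return A symmetric numeric matrix (samples x samples) with zero
#'   diagonal and sample ids as dimnames.
#' @export
pav_distance <- function(pav) {
  stopifnot(inherits(pav, "pav_matrix"), ncol(pav$presence) >= 2L)
  x <- t(pav$presence)
  d <- as.matrix(stats::dist(x, method = "manhattan")) / ncol(x)
  dimnames(d) <- list(pav$sample_ids, pav$sample_ids)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair `(i, j)`
#' minimising `Q(i,j) = (r - 2) d(i,j) - R_i - R_j` (with `R_i` the row sum
#' over the `r` active nodes) is joined; branch lengths follow the standard
#' formulas and the new node's distances are
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties on Q are broken by the
#' first pair in row-major order over the current active nodes (input
#' order), so the result is deterministic. Negative branch lengths are
#' clamped to zero and the total clamped deficit reported via a message.
#'
#' @param dist A symmetric numeric matrix with zero diagonal and at least
#'   3 rows; dimnames are used as tip labels (generated if absent).
#' @return An unrooted `phylo` tree (basal trifurcation), as used
#'   throughout the \pkg{ape} ecosystem.
#' @export
neighbor_joining <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist), nrow(dist) >= 3L)
  if (max(abs(dist - t(dist))) > 1e-12)
    stop("neighbor_joining: distance matrix is not symmetric")
  labels <- rownames(dist)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(dist)))
  d <- unname(dist)
  # each active node carries its Newick subtree string
  sub <- labels
  clamped <- 0
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + (-x); 0 } else x
  }
  fmt <- function(s, len) sprintf("%s:%.17g", s, len)

  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, `+`)
    diag(q) <- Inf
    # row-major scan for the minimum => smallest (i, j) pair on ties
    idx <- which(t(q) == min(q))[1L] - 1L
    i <- idx %/% r + 1L
    j <- idx %% r + 1L
    if (i > j) { k <- i; i <- j; j <- k }
    li <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    newsub <- sprintf("(%s,%s)", fmt(sub[i], li), fmt(sub[j], lj))
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    d <- d2
    sub <- c(sub[keep], newsub)
  }
  l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- sprintf("(%s,%s,%s);", fmt(sub[1], l1), fmt(sub[2], l2), fmt(sub[3], l3))
  if (clamped > 0)
    message(sprintf("neighbor_joining: clamped %.6g of negative branch length to 0", clamped))
  ape::read.tree(text = newick)
}

#' Principal component analysis of a PAV matrix
#'
#' Samples are the observations, genes the variables. Gene columns are
#' mean-centred but not variance-scaled (for binary presence data the
#' frequency-weighted variance is informative), and components come from
#' the exact spectral decomposition of the sample covariance. Signs are
#' fixed by making each component's largest-magnitude gene loading
#' positive, so output is reproducible across platforms.
#'
#' @param pav A `pav_matrix` with at least 2 samples.
#' @param k Number of components to return (at most
#'   `min(n_samples - 1, n_genes)`).
#' @return An object of class `pav_pca`: `$scores` (samples x k),
#'   `$loadings` (genes x k), `$var_explained` (fractions of total column
#'   variance), `$total_variance`.
#' @export
pav_pca <- function(pav, k = 2L) {
  stopifnot(inherits(pav, "pav_matrix"), ncol(pav$presence) >= 2L)
  x <- t(pav$presence)
  storage.mode(x) <- "double"
  total_var <- sum(apply(x, 2L, stats::var))
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (k > kmax) stop("k = ", k, " exceeds the available ", kmax, " components")
  if (total_var == 0) {
    warning("constant PAV matrix: zero variance, returning zero components")
    scores <- matrix(0, nrow(x), k, dimnames = list(pav$sample_ids, paste0("PC", 1:k)))
    return(structure(list(scores = scores, loadings = NULL,
                          var_explained = rep(0, k), total_variance = 0),
                     class = "pav_pca"))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- pav$sample_ids
  structure(list(scores = scores, loadings = loadings,
                 var_explained = pc$sdev[seq_len(k)]^2 / total_var,
                 total_variance = total_var),
            class = "pav_pca")
}

#' @export
print.pav_pca <- function(x, ...) {
  cat(sprintf("<pav_pca> %d samples, %d components; variance explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", ")))
  invisible(x)
}
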