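test_that("pav_distance is the per-gene mismatch fraction", {
  m <- matrix(c(1, 1, 0, 0, 1, 0,
                1, 1, 0, 0, 1, 0,
                0, 0, 1, 1, 0, 1,
                1, 0, 0, 1, 1, 0), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  d <- pav_distance(new_pav_matrix(m))
  expect_equal(d["s1", "s2"], 0)          # identical columns
  expect_equal(d["s1", "s3"], 1)          # complementary columns
  brute <- function(i, j) mean(m[, i] != m[, j])
  for (i in 1:4) for (j in 1:4) expect_equal(d[i, j], brute(i, j))
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 4), paste0("s", 1:4)))
})

test_that("pav_distance satisfies the triangle inequality", {
  set.seed(8)
  m <- matrix(rbinom(30 * 12, 1, 0.5), 30, 12,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
  d <- pav_distance(new_pav_matrix(m))
  for (rep in 1:50) {
    ijk <- sample(12, 3)
    expect_lte(d[ijk[1], ijk[3]], d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("three taxa resolve by the closed-form star lengths", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  pl <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(pl, d, tolerance = 1e-12)
  expect_equal(sort(tree$edge.length), sort(c(1, 2, 3)))  # (3+4-5)/2 etc.
})

test_that("NJ inverts a hand-built additive four-taxon matrix", {
  # tree ((A:1,B:2):1,C:3,D:4) gives these path-length distances
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(d)
  pl <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pl, d, tolerance = 1e-9)
  # A and B are sisters
  mrca_ab <- ape::getMRCA(ape::root(tree, "D"), c("A", "B"))
  desc <- ape::extract.clade(ape::root(tree, "D"), mrca_ab)$tip.label
  expect_setequal(desc, c("A", "B"))
})

test_that("NJ reconstructs random additive matrices exactly", {
  set.seed(99)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    true_tree <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    d <- ape::cophenetic.phylo(true_tree)
    ord <- sample(rownames(d))
    d <- d[ord, ord]
    tree <- neighbor_joining(d)
    pl <- ape::cophenetic.phylo(tree)[ord, ord]
    expect_equal(pl, d, tolerance = 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tree), tree)), 0)
  }
})

test_that("NJ agrees with the ape reference implementation", {
  set.seed(55)
  m <- matrix(rbinom(40 * 9, 1, 0.4), 40, 9,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:9)))
  d <- pav_distance(new_pav_matrix(m))
  ours <- suppressMessages(neighbor_joining(d))
  ref <- ape::nj(as.dist(d))
  expect_equal(as.numeric(ape::dist.topo(ours, ref)), 0)
})

test_that("asymmetric distance input is rejected", {
  d <- matrix(runif(16), 4); diag(d) <- 0
  expect_error(neighbor_joining(d), "not symmetric")
})

test_that("PCA separates two planted clusters on PC1", {
  genes <- paste0("g", 1:30)
  m <- matrix(1L, 30, 10, dimnames = list(genes, paste0("s", 1:10)))
  m[1:10, 6:10] <- 0L    # cluster 2 lacks ten genes
  pc <- pav_pca(new_pav_matrix(m), k = 2)
  expect_gt(abs(mean(pc$scores[1:5, 1]) - mean(pc$scores[6:10, 1])), 1)
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-12)
})

test_that("PCA matches a direct eigendecomposition of the covariance", {
  set.seed(21)
  m <- matrix(rbinom(8 * 5, 1, 0.5), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  pav <- new_pav_matrix(m)
  pc <- pav_pca(pav, k = 3)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(x), symmetric = TRUE)
  scores_ref <- x %*% eig$vectors[, 1:3]
  for (j in 1:3)  # compare up to sign
    expect_equal(abs(unname(pc$scores[, j])), abs(unname(scores_ref[, j])),
                 tolerance = 1e-8)
  expect_equal(sum(pc$var_explained),
               sum(eig$values[1:3]) / sum(diag(stats::cov(x))), tolerance = 1e-10)
})

test_that("total explained variance is conserved and signs are fixed", {
  d <- small_design(seed = 19)
  sim <- simulate_pav_study(d)
  kmax <- min(d$n_samples - 1L, d$n_genes)
  pc <- pav_pca(sim$truth, k = kmax)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-10)
  for (j in seq_len(ncol(pc$loadings)))
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
})

test_that("constant matrix yields zero components with a warning", {
  m <- matrix(1L, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_warning(pc <- pav_pca(new_pav_matrix(m), k = 2), "zero variance")
  expect_true(all(pc$scores == 0))
})

test_that("newick output round-trips topology and branch lengths", {
  set.seed(4)
  t1 <- ape::rtree(7)
  d <- ape::cophenetic.phylo(t1)
  tree <- neighbor_joining(d)
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tree, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[rownames(d), colnames(d)],
               ape::cophenetic.phylo(tree)[rownames(d), colnames(d)],
               tolerance = 1e-8)
})
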