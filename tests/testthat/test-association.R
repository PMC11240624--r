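test_that("deregress divides PTA by reliability and propagates NAs", {
  expect_equal(deregress(0.5, 0.8), 0.625)
  expect_equal(deregress(3.2, 1.0), 3.2)
  expect_true(is.na(deregress(NA, 0.9)))
  expect_error(deregress(1, 0), "> 0")
  expect_error(deregress(1, -0.2), "> 0")
})

test_that("deregress inverts the simulated PTA construction exactly", {
  d <- small_design(seed = 26)
  sim <- simulate_pav_study(d)
  tt <- trait_table(sim$phenotypes)
  expect_equal(tt$dpta[rownames(sim$dpta_truth), colnames(sim$dpta_truth)],
               sim$dpta_truth)
})

test_that("trait correlations match the closed-form Pearson formula", {
  set.seed(2)
  x <- rnorm(10); y <- 0.6 * x + rnorm(10)
  ph <- rbind(data.frame(sample_id = paste0("s", 1:10), trait = "A",
                         pta = x, reliability = 1),
              data.frame(sample_id = paste0("s", 1:10), trait = "B",
                         pta = y, reliability = 1),
              data.frame(sample_id = paste0("s", 1:10), trait = "C",
                         pta = -x, reliability = 1))
  ct <- trait_correlations(trait_table(ph))
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r["A", "B"], r_brute, tolerance = 1e-12)
  expect_equal(ct$r["A", "A"], 1)
  expect_equal(ct$r["A", "C"], -1)
  expect_equal(ct$p["A", "B"], stats::cor.test(x, y)$p.value, tolerance = 1e-12)
  expect_true(isSymmetric(ct$r))
})

test_that("zero-variance traits are flagged NA, not fabricated", {
  ph <- rbind(data.frame(sample_id = paste0("s", 1:5), trait = "A",
                         pta = 1:5, reliability = 1),
              data.frame(sample_id = paste0("s", 1:5), trait = "FLAT",
                         pta = 2, reliability = 1))
  ct <- trait_correlations(trait_table(ph))
  expect_true(is.na(ct$r["A", "FLAT"]))
})

test_that("MAF filter retains markers with min(f, 1-f) strictly above cutoff", {
  n <- 154L
  counts <- c(a = round(0.97 * n), b = round(0.5 * n), c = round(0.03 * n),
              d = 0L, e = n, f = round(0.06 * n))
  m <- matrix(0L, length(counts), n,
              dimnames = list(names(counts), paste0("s", seq_len(n))))
  for (i in seq_along(counts)) if (counts[i] > 0) m[i, seq_len(counts[i])] <- 1L
  pav <- new_pav_matrix(m)
  kept <- maf_filter(pav, 0.05)
  f <- rowMeans(m)
  expect_setequal(kept, names(which(pmin(f, 1 - f) > 0.05)))
  expect_true("b" %in% kept)       # f = 0.5
  expect_false("a" %in% kept)      # MAF 0.03
  expect_false(any(c("d", "e") %in% kept))  # monomorphic
})

test_that("glm_assoc matches anova(lm()) and the pooled t-squared identity", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    g <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(g)) < 2) next
    y <- rnorm(n) + g * rnorm(1)
    res <- glm_assoc(g, y)
    ref <- anova(lm(y ~ g))
    expect_equal(res$F, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(res$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
    tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("glm_assoc handles degenerate inputs", {
  expect_equal(glm_assoc(c(0, 1, 0, 1), c(2, 2, 2, 2))$F, 0)
  expect_equal(glm_assoc(c(0, 1, 0, 1), c(2, 2, 2, 2))$p, 1)
  expect_null(glm_assoc(c(1, 1, 1, 1), rnorm(4)))       # one genotype class
  expect_null(glm_assoc(c(0, 1), rnorm(2)))             # too few samples
  # casewise deletion emptying a class
  expect_null(glm_assoc(c(0, 0, 0, 1), c(1, 2, 3, NA)))
})

test_that("Bonferroni tiers reproduce the published cohort's thresholds", {
  # 487 loci: significant <= 1.0267e-4 < suggestive <= 2.0534e-4
  expect_equal(as.character(bonferroni_tier(5.99e-5, 487)), "significant")
  expect_equal(as.character(bonferroni_tier(1.01e-4, 487)), "significant")
  expect_equal(as.character(bonferroni_tier(1.90e-4, 487)), "suggestive")
  expect_equal(as.character(bonferroni_tier(2.06e-4, 487)), "none")
})

test_that("bonferroni_tier is monotone in p and n_loci", {
  p <- sort(runif(50, 1e-6, 1))
  tiers <- as.integer(bonferroni_tier(p, 100))
  expect_true(all(diff(tiers) >= 0))
  for (pp in c(1e-4, 5e-4, 2e-3))
    expect_gte(as.integer(bonferroni_tier(pp, 200)),
               as.integer(bonferroni_tier(pp, 100)))
})

test_that("run_gwas finds a strong planted effect as the top significant hit", {
  d <- small_design(seed = 33,
                    causal = data.frame(trait = "T01", frequency = 0.4, beta = 3))
  genes <- simulate_annotation(d)
  pr <- simulate_presence(d, genes)
  ph <- simulate_phenotypes(d, pr)
  gw <- run_gwas(pr$truth, trait_table(ph$phenotypes), genes = genes)
  top <- gw[gw$trait == "T01", ][1, ]
  expect_equal(top$gene_id, pr$causal$gene_id)
  expect_equal(as.character(top$tier), "significant")
  # per-trait sort by p
  for (tr in unique(gw$trait))
    expect_false(is.unsorted(gw$p[gw$trait == tr]))
})

test_that("run_gwas respects sample intersection and chromosome filters", {
  d <- small_design(seed = 34)
  genes <- simulate_annotation(d)
  pr <- simulate_presence(d, genes)
  ph <- simulate_phenotypes(d, pr)
  ph$phenotypes <- ph$phenotypes[ph$phenotypes$sample_id != "s001", ]
  gw <- run_gwas(pr$truth, trait_table(ph$phenotypes), genes = genes,
                 chrom_filter = "chr1")
  expect_true(all(gw$chrom == "chr1"))
  expect_true(all(gw$n_used <= d$n_samples - 1L))
  # markers = MAF-passing chr1 genes, frequencies on the phenotyped subset
  shared <- setdiff(pr$truth$sample_ids, "s001")
  f <- rowMeans(pr$truth$presence[, shared])
  chr1 <- vapply(genes, function(g) g$chrom == "chr1", logical(1))
  expect_equal(attr(gw, "n_loci"),
               sum(pmin(f, 1 - f) > 0.05 & chr1[names(f)]))
  expect_error(run_gwas(pr$truth, trait_table(ph$phenotypes), genes = genes,
                        maf_threshold = 0.499),
               "survive")
})

test_that("fisher_enrichment equals the hypergeometric tail", {
  # 2x2 table (8,2; 10,80): overlap 8, query 18, set 10, background 100
  bg <- paste0("g", 1:100)
  query <- bg[1:18]
  sets <- list(hit = bg[c(1:8, 19:20)])
  res <- fisher_enrichment(query, bg, sets)
  expect_equal(res$p, brute_fisher_p(8, 18, 10, 100), tolerance = 1e-12)
  expect_equal(res$overlap, 8)
})

test_that("an exactly-matching disjoint set is the minimal-p enrichment", {
  bg <- paste0("g", 1:60)
  sets <- list(A = bg[1:10], B = bg[11:20], C = bg[21:30])
  res <- fisher_enrichment(query = bg[1:10], background = bg,
                           annotation_sets = sets)
  expect_equal(res$set[1], "A")
  expect_true(res$enriched[1])
  expect_false(any(res$enriched[-1]))
  expect_error(fisher_enrichment(c("zzz"), bg, sets), "outside the background")
  expect_error(fisher_enrichment(character(), character(), sets), "empty background")
})

test_that("BH-adjusted FDR is monotone in p-rank", {
  set.seed(3)
  bg <- paste0("g", 1:200)
  sets <- lapply(1:12, function(i) sample(bg, 25))
  names(sets) <- paste0("set", 1:12)
  res <- fisher_enrichment(sample(bg, 40), bg, sets)
  expect_false(is.unsorted(res$fdr))
  expect_equal(res$fdr, stats::p.adjust(res$p, "BH"))
})
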