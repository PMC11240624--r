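test_that("merge_intervals merges overlapping and touching intervals", {
  expect_equal(merge_intervals(data.frame(start = c(0L, 5L), end = c(10L, 15L))),
               data.frame(start = 0L, end = 15L))
  expect_equal(merge_intervals(data.frame(start = c(0L, 10L), end = c(10L, 20L))),
               data.frame(start = 0L, end = 20L))
  expect_error(merge_intervals(data.frame(chrom = c("chr1", "chr2"),
                                          start = c(0L, 0L), end = c(5L, 5L))),
               "multiple chromosomes")
})

test_that("merge_intervals equals brute-force base-set union", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    start <- sample(0:9000, n, replace = TRUE)
    iv <- data.frame(start = start, end = start + sample(1:500, n, replace = TRUE))
    m <- merge_intervals(iv)
    bases <- sort(unique(unlist(Map(function(s, e) s:(e - 1L), iv$start, iv$end))))
    mbases <- unlist(Map(function(s, e) s:(e - 1L), m$start, m$end))
    expect_identical(mbases, bases)
    # merged intervals are sorted, disjoint and non-adjacent
    if (nrow(m) > 1L) expect_true(all(m$start[-1L] > m$end[-nrow(m)]))
  }
})

test_that("select_longest maximises exonic length with lexicographic ties", {
  g <- toy_gene(exons_by_tx = list(
    t1 = data.frame(start = c(0L, 600L), end = c(600L, 1200L)),   # 1200 bp
    t2 = data.frame(start = 0L, end = 800L)))                      # 800 bp
  expect_equal(g$longest$transcript_id, "t1")
  expect_equal(g$longest$exonic_length, 1200L)

  tie <- toy_gene(exons_by_tx = list(
    tB = data.frame(start = 0L, end = 900L),
    tA = data.frame(start = 1000L, end = 1900L)))
  expect_equal(tie$longest$transcript_id, "tA")
})

test_that("exonic length counts distinct bases, not genomic span", {
  # wide-span transcript with 100 exonic bases loses to compact 150 bp one
  g <- toy_gene(exons_by_tx = list(
    wide = data.frame(start = c(0L, 950L), end = c(50L, 1000L)),
    compact = data.frame(start = 0L, end = 150L)))
  expect_equal(g$longest$transcript_id, "compact")
  span <- max(g$longest$exons$end) - min(g$longest$exons$start)
  expect_lte(sum(g$exon_union$end - g$exon_union$start), span)
})

test_that("select_longest is idempotent and transcript-order invariant", {
  txs <- list(
    t1 = data.frame(start = c(0L, 200L), end = c(100L, 350L)),
    t2 = data.frame(start = 0L, end = 120L),
    t3 = data.frame(start = c(0L, 500L), end = c(90L, 580L)))
  g1 <- toy_gene(exons_by_tx = txs)
  g2 <- toy_gene(exons_by_tx = txs[c(3, 1, 2)])
  expect_equal(g1$longest$transcript_id, g2$longest$transcript_id)
  expect_equal(select_longest(g1)$longest, g1$longest)
})

test_that("parse_gff3 converts 1-based inclusive to 0-based half-open", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t200\t.\t+\t.\tID=gX",
    "chr1\tx\tmRNA\t101\t200\t.\t+\t.\tID=gX.t1;Parent=gX",
    "chr1\tx\texon\t101\t200\t.\t+\t.\tID=gX.t1.e1;Parent=gX.t1"), gff)
  genes <- parse_gff3(gff)
  expect_length(genes, 1L)
  expect_equal(genes$gX$exon_union, data.frame(start = 100L, end = 200L))
  expect_equal(genes$gX$longest$exonic_length, 100L)
})

test_that("parse_gff3 keeps multi-transcript structure and flags orphans", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t900\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tx\texon\t1\t100\t.\t+\t.\tID=e1;Parent=g1.t1",
    "chr1\tx\texon\t201\t300\t.\t+\t.\tID=e2;Parent=g1.t1",
    "chr1\tx\texon\t401\t500\t.\t+\t.\tID=e3;Parent=g1.t1",
    "chr1\tx\tmRNA\t1\t500\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tx\texon\t1\t150\t.\t+\t.\tID=e4;Parent=g1.t2",
    "chr1\tx\texon\t301\t400\t.\t+\t.\tID=e5;Parent=g1.t2"), gff)
  genes <- parse_gff3(gff)
  expect_length(genes$g1$transcripts, 2L)
  expect_equal(nrow(genes$g1$transcripts[["g1.t1"]]$exons), 3L)

  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tx\texon\t1\t100\t.\t+\t.\tID=e1;Parent=ghost"), bad)
  expect_error(parse_gff3(bad), "unknown Parent")
})

test_that("genes without exon-bearing transcripts are dropped with a warning", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=gOK",
    "chr1\tx\tmRNA\t1\t100\t.\t+\t.\tID=gOK.t1;Parent=gOK",
    "chr1\tx\texon\t1\t100\t.\t+\t.\tID=e1;Parent=gOK.t1",
    "chr1\tx\tgene\t201\t300\t.\t+\t.\tID=gEmpty"), gff)
  expect_warning(genes <- parse_gff3(gff), "excluded")
  expect_identical(names(genes), "gOK")
})

test_that("filter_chromosomes keeps allowed chromosomes in order", {
  genes <- list(
    a = toy_gene("a", "chr1", list(data.frame(start = 0L, end = 10L))),
    b = toy_gene("b", "chrX", list(data.frame(start = 0L, end = 10L))),
    c = toy_gene("c", "chr2", list(data.frame(start = 0L, end = 10L))))
  kept <- filter_chromosomes(genes, c("chr1", "chr2"))
  expect_identical(names(kept), c("a", "c"))
  expect_identical(filter_chromosomes(genes, c("chr1", "chrX", "chr2")), genes)
})

test_that("synthetic GFF3 round-trips through parse_gff3", {
  d <- small_design(seed = 5)
  gff <- tempfile(fileext = ".gff3")
  genes <- simulate_annotation(d, gff3_path = gff)
  back <- parse_gff3(gff)
  expect_identical(sort(names(back)), sort(names(genes)))
  for (id in names(genes)) {
    expect_equal(back[[id]]$chrom, genes[[id]]$chrom)
    expect_equal(back[[id]]$strand, genes[[id]]$strand)
    expect_equal(back[[id]]$exon_union, genes[[id]]$exon_union)
    expect_equal(back[[id]]$longest$transcript_id, genes[[id]]$longest$transcript_id)
    expect_equal(back[[id]]$category, genes[[id]]$category)
  }
})
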