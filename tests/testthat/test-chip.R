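# Consensus peaks, TSS distances, feature annotation, differential binding,
# integration and qPCR arithmetic, against hand computations and exhaustive
# oracles.

test_that("consensus of identical replicates is the replicate set", {
  gr <- peak_set(rep("chr1", 3), c(100, 1000, 5000), c(300, 1400, 5200))
  cons <- build_consensus(list(gr, gr, gr), min_support = 2, min_width = 50)
  expect_equal(GenomicRanges::start(cons), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(cons), GenomicRanges::end(gr))
})

test_that("consensus matches the hand-counted overlap example", {
  r1 <- peak_set("chr1", 100, 200)
  r2 <- peak_set("chr1", 150, 250)
  r3 <- peak_set("chr1", 400, 500)
  cons <- build_consensus(list(r1, r2, r3), min_support = 2, min_width = 50)
  expect_length(cons, 1)
  # 0-based half-open [150, 200): bases covered by two replicates
  expect_equal(GenomicRanges::start(cons) - 1L, 150L)
  expect_equal(GenomicRanges::end(cons), 200L)
})

test_that("consensus equals the per-base coverage oracle on random intervals", {
  set.seed(61)
  glen <- 100000L
  for (i in 1:5) {
    reps <- lapply(1:3, function(k) random_intervals(80, glen, max_width = 800))
    grs <- lapply(reps, function(df) peak_set("chr1", df$start, df$end))
    cons <- build_consensus(grs, min_support = 2, min_width = 50)
    oracle <- brute_consensus(reps, glen, min_support = 2, min_width = 50)
    expect_equal(GenomicRanges::start(cons) - 1L, oracle$start)
    expect_equal(GenomicRanges::end(cons), oracle$end)
  }
})

test_that("consensus is idempotent on copies of its own output", {
  set.seed(62)
  reps <- lapply(1:3, function(k) {
    df <- random_intervals(60, 50000, max_width = 400)
    peak_set("chr1", df$start, df$end)
  })
  cons <- build_consensus(reps, min_support = 2, min_width = 50)
  again <- build_consensus(list(cons, cons, cons), min_support = 3, min_width = 1)
  expect_equal(GenomicRanges::start(again), GenomicRanges::start(cons))
  expect_equal(GenomicRanges::end(again), GenomicRanges::end(cons))
})

test_that("min_support beyond the replicate count is a configuration error", {
  gr <- peak_set("chr1", 10, 100)
  expect_error(build_consensus(list(gr, gr), min_support = 3), "min_support")
})

test_that("peaks and annotation round-trip through BED losslessly", {
  gr <- peak_set(c("chr1", "chr2"), c(0, 999), c(250, 2000), score = c(1.5, 7))
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks(gr, path)
  back <- read_peaks(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(S4Vectors::mcols(back)$score, S4Vectors::mcols(gr)$score)

  genes <- gene_annotation(c("gA", "gB"), c("chr1", "chr2"), c(100, 5000),
                           c(2100, 9000), c("+", "-"))
  gpath <- withr::local_tempfile(fileext = ".bed")
  write_gene_annotation(genes, gpath)
  gback <- read_gene_annotation(gpath)
  expect_equal(gback, genes)
})

test_that("TSS derivation and signed distances follow the strand convention", {
  genes <- gene_annotation("gA", "chr1", 1000, 2000, "-")
  expect_equal(genes$tss, 1999L)
  # peak center 1980 lies downstream of the minus-strand TSS: distance -19
  pk <- peak_set("chr1", 1900, 2060)
  asg <- assign_nearest_tss(pk, genes)
  expect_equal(asg$distance, -19L)

  # plus-strand gene, peak centered exactly on the TSS
  gplus <- gene_annotation("gB", "chr1", 500, 1500, "+")
  pk0 <- peak_set("chr1", 400, 600) # center 500 = TSS
  expect_equal(assign_nearest_tss(pk0, gplus)$distance, 0L)
})

test_that("nearest-TSS assignment matches the all-pairs oracle", {
  set.seed(63)
  for (i in 1:5) {
    gs <- sample.int(900000, 50)
    genes <- gene_annotation(
      sprintf("g%03d", 1:50), sample(c("chr1", "chr2"), 50, replace = TRUE),
      gs, gs + sample(5000:20000, 50),
      sample(c("+", "-"), 50, replace = TRUE))
    df <- random_intervals(200, 950000, max_width = 400)
    pk <- peak_set(sample(c("chr1", "chr2", "chr3"), 200, replace = TRUE),
                   df$start, df$end)
    asg <- assign_nearest_tss(pk, genes)
    centers <- (df$start + df$end) %/% 2
    chroms <- as.character(GenomicRanges::seqnames(pk))
    for (k in seq_len(200)) {
      o <- brute_nearest(centers[k], chroms[k], genes)
      expect_identical(asg$gene_id[k], o$gene_id)
      expect_identical(asg$distance[k], o$distance)
    }
  }
})

test_that("distance histogram counts sum to the peak count incl. unassigned", {
  genes <- gene_annotation("gA", "chr1", 10000, 20000, "+")
  pk <- peak_set(c("chr1", "chr1", "chrX"), c(9000, 500000, 100),
                 c(9200, 500400, 300))
  prof <- tss_distance_profile(pk, genes, bins = seq(-5000, 5000, 1000))
  expect_equal(sum(prof$histogram$count), 3)
  expect_equal(prof$histogram$count[prof$histogram$bin == "unassigned"], 1)
})

test_that("feature annotation applies promoter > gene_body precedence", {
  genes <- gene_annotation("gA", "chr1", 10000, 30000, "+")
  # center inside both the promoter window and the gene body
  pk <- peak_set("chr1", 10050, 10350) # center 10200 < TSS + 500
  expect_equal(annotate_regions(pk, genes), "promoter")
  body <- peak_set("chr1", 20000, 20300)
  expect_equal(annotate_regions(body, genes), "gene_body")
  far <- peak_set("chr1", 600000, 600300)
  expect_equal(annotate_regions(far, genes), "intergenic")
})

test_that("feature annotation matches the exhaustive oracle", {
  set.seed(64)
  for (i in 1:5) {
    gs <- sample.int(800000, 40)
    genes <- gene_annotation(
      sprintf("g%03d", 1:40), rep("chr1", 40),
      gs, gs + sample(3000:15000, 40),
      sample(c("+", "-"), 40, replace = TRUE))
    df <- random_intervals(300, 850000, max_width = 300)
    pk <- peak_set("chr1", df$start, df$end)
    got <- annotate_regions(pk, genes, promoter_up = 2000, promoter_down = 500)
    centers <- (df$start + df$end) %/% 2
    want <- vapply(centers, brute_feature, character(1), chrom = "chr1",
                   genes = genes, up = 2000, down = 500)
    expect_equal(got, want)
  }
})

test_that("differential binding is null for identical replicate columns", {
  counts <- matrix(rep(c(100L, 40L, 250L), 6), nrow = 3,
                   dimnames = list(paste0("p", 1:3), paste0("s", 1:6)))
  d <- make_chip_design()
  db <- differential_binding(counts, d, contrast_spec("FFF", "WT", treatment = "R5020"))
  expect_equal(nrow(db$significant), 0)
  expect_equal(db$results$log2FoldChange, rep(0, 3))
})

test_that("differential binding recovers true occupancy shifts and is antisymmetric", {
  truth <- generate_truth(200, c("NULL" = 0.5, ATTENUATED_FFF = 0.5), seed = 65)
  d <- make_chip_design()
  cfg <- chip_config(n_peaks = 200, frac_differential = 0.25, diff_log2fc = 1.5)
  chip <- simulate_chip_data(truth, d, config = cfg, seed = 65)
  fwd <- differential_binding(chip$peak_counts, d,
                              contrast_spec("FFF", "WT", treatment = "R5020"))
  truly <- chip$peak_truth$peak_id[chip$peak_truth$is_differential]
  hit <- fwd$significant$gene_id[fwd$significant$direction == "up"]
  expect_gte(mean(truly %in% hit), 0.8)
  # false discovery among non-differential peaks stays low
  null_peaks <- chip$peak_truth$peak_id[!chip$peak_truth$is_differential]
  expect_lte(mean(null_peaks %in% fwd$significant$gene_id), 0.1)
  rev <- differential_binding(chip$peak_counts, d,
                              contrast_spec("WT", "FFF", treatment = "R5020"))
  expect_equal(rev$results$log2FoldChange, -fwd$results$log2FoldChange)
  expect_equal(rev$results$pvalue, fwd$results$pvalue)
})

test_that("integration summarizes constructed peak-gene links exactly", {
  genes <- gene_annotation(c("gA", "gB", "gC"), rep("chr1", 3),
                           c(10000, 200000, 400000),
                           c(20000, 210000, 410000), c("+", "+", "+"))
  taxonomy <- data.frame(gene_id = c("gA", "gB"),
                         category = c("HYPO", "UNAFFECTED"),
                         stringsAsFactors = FALSE)
  # two peaks at gA (attenuated), one at gB, one intergenic far away
  pk <- peak_set("chr1", c(9800, 10500, 199800, 700000),
                 c(10200, 10900, 200200, 700400))
  S4Vectors::mcols(pk)$db_log2fc <- c(1.5, 1.4, 1.6, 1.2)
  S4Vectors::mcols(pk)$db_fdr <- rep(0.01, 4)
  ig <- integrate_expression(pk, genes, taxonomy, window = 5e4)
  expect_equal(ig$summary$n_differential, 4)
  expect_equal(ig$summary$n_associated, 3)
  expect_equal(ig$summary$frac_associated, 0.75)
  expect_equal(ig$summary$frac_attenuated, 2 / 3)
  expect_equal(ig$summary$frac_other, 1 / 3)
  expect_error(integrate_expression(pk, genes, taxonomy[0, ]), "empty")

  empty <- integrate_expression(pk[0], genes, taxonomy)
  expect_equal(empty$summary$n_differential, 0)
  expect_equal(empty$summary$frac_associated, 0)
})

test_that("qPCR enrichment follows the comparative Ct arithmetic", {
  # identical treated and vehicle Cts: no enrichment
  expect_equal(qpcr_enrichment(25, 20, 25, 20, 0.01)$fold_enrichment, 1)
  # one cycle lower IP Ct in treated: twofold enrichment
  expect_equal(qpcr_enrichment(24, 20, 25, 20, 0.01)$fold_enrichment, 2)
  # full input and equal Cts: percent input is 100%
  expect_equal(qpcr_enrichment(20, 20, 22, 22, 1)$percent_input_treated, 100)
  expect_error(qpcr_enrichment(20, 20, 20, 20, 0), "input_fraction")
  expect_error(qpcr_enrichment(Inf, 20, 20, 20, 0.1), "finite")
})
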