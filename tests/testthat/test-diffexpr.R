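# NB differential-expression engine: normalization, dispersion, Wald
# contrasts and BH adjustment against hand computations and independent
# oracles.

test_that("size factors are 1 for identical columns and match hand computation", {
  m <- matrix(rep(c(10L, 100L, 5L), 3), ncol = 3)
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(compute_size_factors(m)), rep(1, 3))

  m2 <- matrix(c(10L, 100L, 5L, 20L, 200L, 10L), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  sf <- compute_size_factors(m2)
  # every gene ratio is x/sqrt(2x^2) = 1/sqrt(2) in a, sqrt(2) in b
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf["b"] / sf["a"]), 2)
})

test_that("size factors error without an everywhere-positive gene", {
  m <- matrix(c(0L, 5L, 5L, 0L), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(compute_size_factors(m), "filter")
})

test_that("known column scalings are recovered within 2%", {
  set.seed(41)
  cj <- c(0.5, 0.8, 1, 1.25, 2, 3)
  base <- pmax(50, round(stats::rlnorm(200, log(1000), 0.7)))
  m <- sapply(cj, function(c) stats::rpois(200, base * c))
  dimnames(m) <- list(paste0("g", 1:200), paste0("s", 1:6))
  sf <- compute_size_factors(m)
  rel <- (sf / cj) / exp(mean(log(sf / cj))) # up to global scale
  expect_lt(max(abs(rel - 1)), 0.02)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(42)
  m <- matrix(stats::rpois(600, rep(c(50, 200, 800), each = 200) *
                             rep(c(0.7, 1, 1.6), 200)),
              nrow = 200, byrow = FALSE)
  m <- m + 1L
  dimnames(m) <- list(paste0("g", 1:200), paste0("s", 1:3))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref))) # common unit-geometric-mean convention
  expect_equal(unname(compute_size_factors(m)), unname(ref), tolerance = 1e-10)
})

test_that("raw method-of-moments dispersion matches plug-in arithmetic", {
  # counts 70,100,100,130: mean 100, variance 600 => (600-100)/100^2 = 0.05
  counts <- matrix(c(70L, 100L, 100L, 130L), 1, 4,
                   dimnames = list("g1", paste0("s", 1:4)))
  counts <- rbind(counts, g2 = c(90L, 110L, 95L, 105L))
  d <- data.frame(sample_id = paste0("s", 1:4), cell_line = "WT",
                  treatment = "VEH", replicate = 1:4, assay = "RNA")
  est <- estimate_dispersions(counts, rep(1, 4), d)
  expect_equal(est$disp_raw[est$gene_id == "g1"], 0.05)
})

test_that("dispersion estimates approach 0 for Poisson data", {
  truth <- generate_truth(300, c("NULL" = 1), effect_config(dispersion = 0), seed = 21)
  d <- make_rna_design(cell_lines = "WT", treatments = "VEH", n_rep = 50)
  sim <- simulate_expression_counts(truth, d, seed = 21,
                                    size_factors = rep(1, nrow(d)))
  est <- estimate_dispersions(sim$counts, rep(1, nrow(d)), d)
  expect_lt(stats::median(est$disp), 0.01)
})

test_that("single-replicate designs degrade to trend-only with a flag", {
  counts <- matrix(c(100L, 60L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  d <- data.frame(sample_id = "s1", cell_line = "WT", treatment = "VEH",
                  replicate = 1, assay = "RNA")
  est <- estimate_dispersions(counts, 1, d)
  expect_true(all(est$status == "trend_only"))
  expect_true(all(est$disp >= 0))
})

test_that("Wald contrast is a null identity for equal condition means", {
  counts <- matrix(rep(c(50L, 500L), 4), nrow = 2,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  d <- data.frame(sample_id = paste0("s", 1:4), cell_line = "WT",
                  treatment = rep(c("VEH", "R5020"), each = 2),
                  replicate = c(1, 2, 1, 2), assay = "RNA")
  de <- wald_test(counts, rep(1, 4), rep(0.05, 2), d,
                  contrast_spec("R5020", "VEH", cell_line = "WT"))
  expect_equal(de$log2FoldChange, c(0, 0))
  expect_equal(de$pvalue, c(1, 1))
})

test_that("Poisson-limit Wald p agrees with the exact binomial oracle", {
  counts <- matrix(c(10L, 30L), 1, 2, dimnames = list("g1", c("s1", "s2")))
  d <- data.frame(sample_id = c("s1", "s2"), cell_line = "WT",
                  treatment = c("VEH", "R5020"), replicate = c(1, 1),
                  assay = "RNA")
  suppressWarnings(
    de <- wald_test(counts, c(1, 1), 0, d,
                    contrast_spec("R5020", "VEH", cell_line = "WT"))
  )
  exact <- stats::binom.test(30, 40, 0.5)$p.value
  expect_equal(de$log2FoldChange, log2(3))
  # documented normal-approximation tolerance: within a factor of 1.5
  expect_lt(de$pvalue / exact, 1.5)
  expect_gt(de$pvalue / exact, 1 / 1.5)
})

test_that("log2 fold changes are antisymmetric and p-values swap-invariant", {
  truth <- generate_truth(100, c("NULL" = 0.5, LIGAND_UP = 0.5), seed = 22)
  d <- make_rna_design(cell_lines = "WT", treatments = c("VEH", "R5020"), n_rep = 3)
  sim <- simulate_expression_counts(truth, d, seed = 22)
  sf <- compute_size_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, sf, d)
  fwd <- wald_test(sim$counts, sf, disp, d, contrast_spec("R5020", "VEH", cell_line = "WT"))
  rev <- wald_test(sim$counts, sf, disp, d, contrast_spec("VEH", "R5020", cell_line = "WT"))
  expect_equal(fwd$log2FoldChange, -rev$log2FoldChange)
  expect_equal(fwd$pvalue, rev$pvalue)
})

test_that("scaling one sample's counts rescales its factor and leaves results unchanged", {
  truth <- generate_truth(150, c("NULL" = 1), seed = 23)
  truth$base_mean <- pmax(truth$base_mean, 50)
  d <- make_rna_design(cell_lines = "WT", treatments = c("VEH", "R5020"), n_rep = 3)
  sim <- simulate_expression_counts(truth, d, seed = 23)
  ctr <- contrast_spec("R5020", "VEH", cell_line = "WT")
  sf1 <- compute_size_factors(sim$counts)
  de1 <- wald_test(sim$counts, sf1, estimate_dispersions(sim$counts, sf1, d), d, ctr)
  scaled <- sim$counts
  scaled[, 3] <- scaled[, 3] * 5L
  sf2 <- compute_size_factors(scaled)
  # up to the global scale (the scaled column enters every geometric mean),
  # the rescaled sample's factor gains exactly the factor 5
  r <- sf2 / sf1
  expect_equal(unname(r / r[1]), c(1, 1, 5, 1, 1, 1), tolerance = 1e-12)
  # the NB likelihood weighs samples by their exposure, so inference is
  # invariant up to that reweighting and the global normalization scale
  de2 <- wald_test(scaled, sf2, estimate_dispersions(scaled, sf2, d), d, ctr)
  expect_lt(max(abs(de2$log2FoldChange - de1$log2FoldChange)), 0.1)
  expect_lt(mean(abs(de2$log2FoldChange - de1$log2FoldChange)), 0.01)
  expect_gt(stats::cor(de2$stat, de1$stat), 0.999)
})

test_that("all-zero genes are untestable and excluded from the BH denominator", {
  counts <- matrix(c(0L, 0L, 0L, 0L,
                     40L, 60L, 220L, 180L,
                     30L, 35L, 28L, 33L), 3, 4, byrow = TRUE,
                   dimnames = list(c("g0", "g1", "g2"), paste0("s", 1:4)))
  d <- data.frame(sample_id = paste0("s", 1:4), cell_line = "WT",
                  treatment = rep(c("VEH", "R5020"), each = 2),
                  replicate = c(1, 2, 1, 2), assay = "RNA")
  de <- wald_test(counts, rep(1, 4), rep(0.05, 3), d,
                  contrast_spec("R5020", "VEH", cell_line = "WT"))
  expect_equal(de$status, c("untestable", "ok", "ok"))
  expect_true(is.na(de$pvalue[1]) && is.na(de$padj[1]))
  expect_equal(de$padj[-1], adjust_bh(de$pvalue[-1]))
})

test_that("BH adjustment matches hand computations and rejects NaN", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(adjust_bh(c(0.1, NaN)), "NaN")
  expect_error(adjust_bh(c(0.1, 1.2)), "0, 1")
  expect_equal(adjust_bh(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))
})

test_that("BH equals the brute-force step-up definition on random vectors", {
  set.seed(24)
  for (i in 1:50) {
    m <- sample.int(200, 1)
    p <- stats::runif(m)^sample(c(1, 2, 4), 1)
    expect_equal(adjust_bh(p), brute_bh(p))
  }
})

test_that("type-I error is near nominal on null simulations", {
  truth <- generate_truth(1500, c("NULL" = 1), effect_config(dispersion = 0.05),
                          seed = 25)
  d <- make_rna_design(cell_lines = "WT", treatments = c("VEH", "R5020"), n_rep = 3)
  sim <- simulate_expression_counts(truth, d, seed = 25)
  sf <- compute_size_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, sf, d)
  de <- wald_test(sim$counts, sf, disp, d, contrast_spec("R5020", "VEH", cell_line = "WT"))
  expect_gt(mean(de$pvalue < 0.05, na.rm = TRUE), 0.03)
  expect_lt(mean(de$pvalue < 0.05, na.rm = TRUE), 0.07)
})

test_that("strong effects at base mean 500 are detected with high power", {
  eff <- effect_config(lfc_min = 1.5, lfc_max = 1.5, dispersion = 0.05,
                       base_mean_meanlog = log(500), base_mean_sdlog = 0,
                       base_mean_min = 500)
  truth <- generate_truth(2000, c("NULL" = 0.9, LIGAND_UP = 0.1), eff, seed = 26)
  d <- make_rna_design(cell_lines = "WT", treatments = c("VEH", "R5020"), n_rep = 2)
  sim <- simulate_expression_counts(truth, d, seed = 26)
  sf <- compute_size_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, sf, d)
  de <- wald_test(sim$counts, sf, disp, d, contrast_spec("R5020", "VEH", cell_line = "WT"))
  up <- truth$gene_id[truth$archetype == "LIGAND_UP"]
  expect_gte(mean(up %in% call_regulated(de, 0.05)), 0.8)
})

test_that("engine log2 fold changes track DESeq2 on a shared fixture", {
  truth <- generate_truth(200, c("NULL" = 0.5, LIGAND_UP = 0.5), seed = 27)
  d <- make_rna_design(cell_lines = "WT", treatments = c("VEH", "R5020"), n_rep = 3)
  sim <- simulate_expression_counts(truth, d, seed = 27)
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    sim$counts, data.frame(treatment = factor(d$treatment, c("VEH", "R5020"))),
    ~treatment))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  sf <- compute_size_factors(sim$counts)
  de <- wald_test(sim$counts, sf, estimate_dispersions(sim$counts, sf, d), d,
                  contrast_spec("R5020", "VEH", cell_line = "WT"))
  expect_gt(stats::cor(de$log2FoldChange, ref$log2FoldChange), 0.98)
})
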