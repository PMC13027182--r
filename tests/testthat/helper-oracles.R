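# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-base counting, all-pairs scans, literal step-up
# definition) so they cannot share a defect with the implementation.

# literal Benjamini-Hochberg step-up: padj_(i) = min_{j >= i} m * p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# per-base coverage counting on a small genome; returns 0-based half-open
# runs covered by >= min_support replicate sets, width-filtered
brute_consensus <- function(rep_list, genome_len, min_support, min_width,
                            chrom = "chr1") {
  cov <- integer(genome_len)
  for (df in rep_list) {
    hit <- integer(genome_len)
    for (k in seq_len(nrow(df))) {
      hit[(df$start[k] + 1):df$end[k]] <- 1L
    }
    cov <- cov + hit
  }
  keep <- cov >= min_support
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  runs <- runs[runs$end - runs$start >= min_width, , drop = FALSE]
  runs$chrom <- chrom
  runs[, c("chrom", "start", "end")]
}

# exhaustive nearest-TSS search (ties -> lower gene_id)
brute_nearest <- function(center, chrom, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance = NA_integer_))
  d <- abs(center - g$tss)
  cand <- which(d == min(d))
  best <- cand[order(g$gene_id[cand])][1]
  signed <- if (g$strand[best] == "+") g$tss[best] - center else center - g$tss[best]
  list(gene_id = g$gene_id[best], distance = as.integer(signed))
}

# exhaustive promoter/gene_body/intergenic classification of a 0-based
# center position
brute_feature <- function(center, chrom, genes, up, down) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return("intergenic")
  off <- ifelse(g$strand == "+", center - g$tss, g$tss - center)
  if (any(off >= -up & off < down)) return("promoter")
  if (any(g$start <= center & center < g$end)) return("gene_body")
  "intergenic"
}

# hand-assembled DE result table for classifier unit tests
make_de <- function(gene_id, lfc, p = rep(1e-6, length(gene_id)),
                    padj = p, status = "ok") {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, baseMean = rep(100, n),
             log2FoldChange = rep_len(lfc, n), lfcSE = rep(0.1, n),
             stat = rep_len(lfc, n) / 0.1, pvalue = rep_len(p, n),
             padj = rep_len(padj, n), status = rep_len(status, n),
             stringsAsFactors = FALSE)
}

# random non-overlapping-ish raw intervals for consensus tests
random_intervals <- function(n, genome_len, max_width = 500) {
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(genome_len - wi, 1) - 1L, integer(1))
  data.frame(start = s, end = s + w)
}

# effect configuration shared by the parameter-recovery fixtures: base
# means anchored near 500 so that recovery reflects the classifiers, not
# low-count power loss
recovery_effect <- function(...) {
  effect_config(base_mean_meanlog = log(500), base_mean_sdlog = 0.5,
                base_mean_min = 100, ...)
}
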