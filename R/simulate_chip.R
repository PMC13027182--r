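# ChIP-Seq simulator: latent peak set with TSS enrichment, jittered/dropped
# replicate peak sets, NB per-peak occupancy counts, and differential
# occupancy linked to attenuated genes.

#' Build the ChIP sample sheet
#'
#' Default mirrors the study design: biological triplicates per condition
#' for the wild-type and FFF lines under progestin.
#'
#' @param cell_lines cell lines to include.
#' @param treatment single treatment arm.
#' @param n_rep replicates per condition (>= 3).
#' @return design data.frame.
#' @export
make_chip_design <- function(cell_lines = c("WT", "FFF"), treatment = "R5020",
                             n_rep = 3) {
  d <- expand.grid(replicate = seq_len(n_rep), cell_line = cell_lines,
                   stringsAsFactors = FALSE)
  d$treatment <- treatment
  d$sample_id <- sprintf("chip_%s_%s_r%d", d$cell_line, d$treatment, d$replicate)
  d$assay <- "CHIP"
  d <- d[, c("sample_id", "cell_line", "treatment", "replicate", "assay")]
  validate_design(d)
  d
}

#' ChIP simulation parameters
#'
#' @param n_peaks latent peaks in the genome.
#' @param tss_enrichment peak-center density ratio inside vs outside the
#'   +/- `tss_window` around TSSs (default 5, the observed promoter-proximal
#'   concentration of receptor binding).
#' @param tss_window half-width of the enriched window (bp).
#' @param peak_width_min,peak_width_max latent peak width range (bp).
#' @param jitter replicate boundary jitter, uniform on `[-jitter, jitter]`.
#' @param dropout per-replicate peak dropout probability.
#' @param frac_differential fraction of latent peaks with true differential
#'   occupancy (mutant vs wild type).
#' @param diff_target_attenuated fraction of differential peaks placed at
#'   TSSs of progestin-attenuated genes (the remainder target regulated but
#'   non-attenuated genes).
#' @param diff_log2fc true occupancy log2 ratio (mutant over wild type) of
#'   differential peaks.
#' @param occupancy_meanlog,occupancy_sdlog log-normal baseline occupancy.
#' @param library_size_spread sd of log ChIP library size factors.
#' @param dispersion NB dispersion of per-peak counts.
#' @return validated parameter list.
#' @export
chip_config <- function(n_peaks = 200, tss_enrichment = 5, tss_window = 5000,
                        peak_width_min = 200, peak_width_max = 400,
                        jitter = 25, dropout = 0.1,
                        frac_differential = 0.25, diff_target_attenuated = 0.8,
                        diff_log2fc = 1.5,
                        occupancy_meanlog = log(100), occupancy_sdlog = 0.5,
                        library_size_spread = 0.2, dispersion = 0.05) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (frac_differential < 0 || frac_differential > 1) {
    stop("frac_differential must lie in [0, 1]")
  }
  if (diff_target_attenuated < 0 || diff_target_attenuated > 1) {
    stop("diff_target_attenuated must lie in [0, 1]")
  }
  if (peak_width_min < 1 || peak_width_max < peak_width_min) {
    stop("need 1 <= peak_width_min <= peak_width_max")
  }
  as.list(environment())
}

# sample one 0-based position uniformly from a set of disjoint intervals
# (given as a data.frame chrom/start/end), using the current RNG stream
sample_position <- function(intervals) {
  w <- intervals$end - intervals$start
  i <- sample.int(nrow(intervals), 1, prob = w)
  list(chrom = intervals$chrom[i],
       pos = intervals$start[i] + sample.int(w[i], 1) - 1L)
}

#' Simulate gene placement, latent ChIP peaks, replicate peak sets and
#' per-peak occupancy counts
#'
#' Gene bodies are placed uniformly on the synthetic genome (default two
#' 10 Mb chromosomes). Latent peak centers are drawn with `tss_enrichment`-
#' fold excess density inside the +/- `tss_window` around TSSs.
#' Differential peaks are centered within 500 bp of target-gene TSSs:
#' `diff_target_attenuated` of them at progestin-attenuated genes, the rest
#' at regulated non-attenuated genes, with true occupancy log2 ratio
#' `diff_log2fc` (mutant over wild type). Replicate peak sets are
#' independently dropped and boundary-jittered copies of the latent set.
#' Per-peak counts are NB around a log-normal baseline occupancy.
#'
#' @param truth truth table from [generate_truth()].
#' @param design ChIP design from [make_chip_design()].
#' @param genome named vector of chromosome lengths.
#' @param config parameters from [chip_config()].
#' @param seed integer master seed.
#' @return list: `replicate_peaks` (named list of GRanges, one per sample),
#'   `peak_counts` (latent peaks x samples), `design`, `annotation` (gene
#'   table), `peak_truth` (per-peak truth: coordinates, `is_differential`,
#'   `true_log2_ratio`, `target_gene_id`), `latent_peaks` (GRanges),
#'   `size_factors`.
#' @export
simulate_chip_data <- function(truth, design, genome = c(chr1 = 1e7, chr2 = 1e7),
                               config = chip_config(), seed = 1) {
  validate_design(design, require_replicates = FALSE)
  if (!all(design$assay == "CHIP")) stop("design assay must be CHIP")
  if (is.null(names(genome)) || any(genome <= 0)) {
    stop("genome must be a named vector of positive chromosome lengths")
  }
  if (config$peak_width_max >= min(genome)) {
    stop("peak width exceeds a chromosome length")
  }
  n_genes <- nrow(truth)

  # gene placement: one substream per gene (salt family 201)
  gene_len_min <- 5000; gene_len_max <- 20000
  chroms <- names(genome)
  ann <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    withr::with_seed(substream_seed(seed, i, salt = 201), {
      chr <- sample(chroms, 1)
      len <- round(stats::runif(1, gene_len_min, gene_len_max))
      start <- sample.int(as.integer(genome[chr] - len), 1) - 1L
      data.frame(chrom = chr, start = start, end = start + len,
                 strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    })
  }))
  annotation <- gene_annotation(truth$gene_id, ann$chrom, ann$start, ann$end,
                                ann$strand)

  # latent peaks: differential peaks pinned to target-gene TSSs, the rest
  # placed by the TSS-enrichment density model
  n_diff <- round(config$frac_differential * config$n_peaks)
  n_diff_att <- round(config$diff_target_attenuated * n_diff)
  att_genes <- truth$gene_id[truth$archetype == "ATTENUATED_FFF"]
  reg_genes <- truth$gene_id[truth$archetype %in%
                               c("LIGAND_UP", "LIGAND_DOWN", "HYPER_QQQ")]
  if (n_diff_att > 0 && !length(att_genes)) {
    stop("differential peaks target attenuated genes but the truth table has none")
  }
  if (n_diff - n_diff_att > 0 && !length(reg_genes)) reg_genes <- att_genes

  win <- GenomicRanges::reduce(GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(annotation$tss - config$tss_window, 0) + 1,
                     pmin(annotation$tss + config$tss_window,
                          genome[annotation$chrom] - 1) + 1)
  ))
  win_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(win)),
                       start = GenomicRanges::start(win) - 1L,
                       end = GenomicRanges::end(win), stringsAsFactors = FALSE)
  gaps <- GenomicRanges::gaps(GenomicRanges::GRanges(
    win_df$chrom, IRanges::IRanges(win_df$start + 1, win_df$end),
    seqlengths = genome))
  gaps <- gaps[GenomicRanges::strand(gaps) == "*"]
  out_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gaps)),
                       start = GenomicRanges::start(gaps) - 1L,
                       end = GenomicRanges::end(gaps), stringsAsFactors = FALSE)
  w_in <- sum(win_df$end - win_df$start)
  w_out <- sum(out_df$end - out_df$start)
  p_in <- config$tss_enrichment * w_in /
    (config$tss_enrichment * w_in + w_out)

  peaks <- vector("list", config$n_peaks)
  tgt <- rep(NA_character_, config$n_peaks)
  for (p in seq_len(config$n_peaks)) {
    drawn <- withr::with_seed(substream_seed(seed, p, salt = 210), {
      wdt <- round(stats::runif(1, config$peak_width_min, config$peak_width_max))
      gene <- NA_character_
      if (p <= n_diff) {
        gene <- if (p <= n_diff_att) {
          att_genes[sample.int(length(att_genes), 1)]
        } else {
          reg_genes[sample.int(length(reg_genes), 1)]
        }
        gi <- match(gene, annotation$gene_id)
        ctr <- annotation$tss[gi] + round(stats::runif(1, -500, 500))
        chr <- annotation$chrom[gi]
      } else {
        loc <- if (stats::runif(1) < p_in) sample_position(win_df) else sample_position(out_df)
        ctr <- loc$pos
        chr <- loc$chrom
      }
      start <- max(0, min(ctr - wdt %/% 2, genome[chr] - wdt))
      list(df = data.frame(chrom = chr, start = start, end = start + wdt,
                           stringsAsFactors = FALSE),
           gene = gene)
    })
    peaks[[p]] <- drawn$df
    tgt[p] <- drawn$gene
  }
  pk <- do.call(rbind, peaks)
  peak_truth <- data.frame(
    peak_id = sprintf("peak_%05d", seq_len(config$n_peaks)),
    chrom = pk$chrom, start = pk$start, end = pk$end,
    is_differential = seq_len(config$n_peaks) <= n_diff,
    true_log2_ratio = ifelse(seq_len(config$n_peaks) <= n_diff,
                             config$diff_log2fc, 0),
    target_gene_id = tgt, stringsAsFactors = FALSE
  )
  latent <- peak_set(pk$chrom, pk$start, pk$end, score = 0,
                     peak_id = peak_truth$peak_id)

  # replicate peak sets: dropout + boundary jitter per sample
  replicate_peaks <- stats::setNames(vector("list", nrow(design)), design$sample_id)
  for (j in seq_len(nrow(design))) {
    replicate_peaks[[j]] <- withr::with_seed(substream_seed(seed, j, salt = 220), {
      keep <- stats::runif(config$n_peaks) >= config$dropout
      st <- pk$start[keep]
      en <- pk$end[keep]
      if (config$jitter > 0) {
        st <- st + round(stats::runif(sum(keep), -config$jitter, config$jitter))
        en <- en + round(stats::runif(sum(keep), -config$jitter, config$jitter))
      }
      st <- pmax(0, st)
      en <- pmin(en, genome[pk$chrom[keep]])
      en <- pmax(en, st + 1)
      peak_set(pk$chrom[keep], st, en, score = 0,
               peak_id = peak_truth$peak_id[keep])
    })
  }

  # per-peak NB occupancy counts on the latent set
  sf <- vapply(seq_len(nrow(design)), function(j) {
    withr::with_seed(substream_seed(seed, j, salt = 230),
                     exp(stats::rnorm(1, 0, config$library_size_spread)))
  }, numeric(1))
  names(sf) <- design$sample_id
  is_mut <- design$cell_line != "WT"
  counts <- matrix(0L, config$n_peaks, nrow(design),
                   dimnames = list(peak_truth$peak_id, design$sample_id))
  for (p in seq_len(config$n_peaks)) {
    counts[p, ] <- withr::with_seed(substream_seed(seed, p, salt = 240), {
      base <- stats::rlnorm(1, config$occupancy_meanlog, config$occupancy_sdlog)
      mu <- base * 2^(peak_truth$true_log2_ratio[p] * is_mut) * sf
      if (config$dispersion == 0) stats::rpois(nrow(design), mu)
      else stats::rnbinom(nrow(design), mu = mu, size = 1 / config$dispersion)
    })
  }

  list(replicate_peaks = replicate_peaks, peak_counts = counts, design = design,
       annotation = annotation, peak_truth = peak_truth, latent_peaks = latent,
       size_factors = sf)
}
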