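# ChIP-Seq consensus peaks, TSS binding profiles, genomic-feature
# annotation, differential occupancy and expression integration.
#
# In memory peaks are GRanges (1-based, Bioconductor convention); on disk
# they are BED-style 0-based half-open. All conversions happen in the I/O
# helpers below, and every distance computation is done on 0-based
# coordinates.

#' Construct a peak set from 0-based half-open intervals
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open bounds (`start < end`).
#' @param score per-peak occupancy score (default 0).
#' @param peak_id identifiers (default `peak_%05d` in input order).
#' @return a `GRanges` with `score` and `peak_id` metadata columns.
#' @export
peak_set <- function(chrom, start, end, score = 0, peak_id = NULL) {
  if (any(start >= end)) stop("peak intervals need start < end (0-based half-open)")
  if (any(start < 0)) stop("peak starts must be nonnegative")
  if (is.null(peak_id)) peak_id <- sprintf("peak_%05d", seq_along(chrom))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  S4Vectors::mcols(gr)$score <- rep_len(score, length(gr))
  S4Vectors::mcols(gr)$peak_id <- peak_id
  gr
}

peak_start0 <- function(gr) GenomicRanges::start(gr) - 1L
peak_end0 <- function(gr) GenomicRanges::end(gr)

# 0-based center position of each peak (midpoint, floor on even widths)
peak_center0 <- function(gr) {
  (peak_start0(gr) + peak_end0(gr)) %/% 2L
}

#' Write / read peaks as BED3+score
#'
#' Tab-separated, no header, columns `chrom`, `start`, `end`, `score` with
#' 0-based half-open coordinates. Round-trips are lossless for intervals
#' and scores; peak ids are regenerated on read.
#'
#' @param peaks GRanges from [peak_set()].
#' @param path file path.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = peak_start0(peaks), end = peak_end0(peaks),
                   score = S4Vectors::mcols(peaks)$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  peak_set(df$chrom, df$start, df$end, score = df$score)
}

#' Write / read gene annotation as BED6
#'
#' Columns `chrom`, `start`, `end`, `gene_id`, `score` (0), `strand`;
#' 0-based half-open. The TSS is derived on read: `start` for `+` genes,
#' `end - 1` for `-` genes.
#'
#' @param genes annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param path file path.
#' @export
write_gene_annotation <- function(genes, path) {
  df <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                   0L, genes$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_annotation
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "start", "end", "gene_id", "score", "strand"))
  gene_annotation(df$gene_id, df$chrom, df$start, df$end, df$strand)
}

#' Build a validated gene annotation table
#'
#' @param gene_id unique identifiers.
#' @param chrom,start,end 0-based half-open gene extents.
#' @param strand `"+"` or `"-"`.
#' @return data.frame with a derived `tss` column (0-based position).
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  if (anyDuplicated(gene_id)) stop("gene_ids must be unique")
  if (any(start >= end)) stop("gene extents need start < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tss <- ifelse(strand == "+", start, end - 1L)
  data.frame(gene_id = gene_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, tss = as.integer(tss),
             row.names = NULL, stringsAsFactors = FALSE)
}

harmonize_seqlevels <- function(peak_list) {
  lv <- unique(unlist(lapply(peak_list, GenomeInfoDb::seqlevels)))
  # common seqlengths so coverage vectors are summable across replicates
  maxend <- vapply(lv, function(chr) {
    max(unlist(lapply(peak_list, function(g) {
      e <- GenomicRanges::end(g)[as.character(GenomicRanges::seqnames(g)) == chr]
      if (length(e)) max(e) else 0L
    })))
  }, numeric(1))
  lapply(peak_list, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    GenomeInfoDb::seqlengths(g) <- maxend
    g
  })
}

#' Consensus peaks by base-pair majority coverage
#'
#' Base pairs covered by at least `min_support` replicate peak sets are
#' retained and merged into maximal runs; runs shorter than `min_width` are
#' discarded. The operation is idempotent: applied to `n` copies of its own
#' output with `min_support = n` it returns the same set.
#'
#' @param replicate_peaks list of >= 2 GRanges (one per replicate).
#' @param min_support minimum number of supporting replicates (<= number of
#'   replicates).
#' @param min_width minimum consensus width in bp.
#' @return GRanges of sorted, non-overlapping consensus peaks; `score` is
#'   the mean replicate coverage over the peak.
#' @export
build_consensus <- function(replicate_peaks, min_support = 2, min_width = 50) {
  if (length(replicate_peaks) < 2) stop("need >= 2 replicate peak sets")
  if (min_support > length(replicate_peaks)) {
    stop("min_support exceeds the number of replicates")
  }
  replicate_peaks <- harmonize_seqlevels(replicate_peaks)
  covs <- lapply(replicate_peaks, function(g) {
    GenomicRanges::coverage(GenomicRanges::reduce(g))
  })
  total <- Reduce(`+`, covs)
  sl <- IRanges::slice(total, lower = min_support, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(sl)
  gr <- gr[GenomicRanges::width(gr) >= min_width]
  gr <- GenomicRanges::sort(gr)
  if (length(gr)) {
    sc <- vapply(seq_along(gr), function(i) {
      chr <- as.character(GenomicRanges::seqnames(gr))[i]
      v <- total[[chr]][GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]]
      mean(as.numeric(v))
    }, numeric(1))
  } else {
    sc <- numeric(0)
  }
  S4Vectors::mcols(gr)$score <- sc
  S4Vectors::mcols(gr)$peak_id <- sprintf("consensus_%05d", seq_along(gr))
  gr
}

#' Nearest-TSS assignment with signed, strand-oriented distances
#'
#' Each peak is assigned to the TSS nearest to its center (ties broken by
#' lower `gene_id`; genes sharing a TSS are represented by their lowest
#' `gene_id`). The signed distance is positive when the peak lies upstream
#' of the TSS in the gene's transcriptional orientation:
#' `tss - center` for `+` genes and `center - tss` for `-` genes. Peaks on
#' chromosomes absent from the annotation are left unassigned.
#'
#' @param peaks GRanges.
#' @param genes annotation from [gene_annotation()].
#' @return data.frame `peak_id`, `gene_id` (NA when unassigned),
#'   `distance` (signed bp, NA when unassigned).
#' @export
assign_nearest_tss <- function(peaks, genes) {
  if (!nrow(genes)) stop("gene annotation is empty")
  centers <- peak_center0(peaks)
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  out <- data.frame(peak_id = S4Vectors::mcols(peaks)$peak_id,
                    gene_id = NA_character_, distance = NA_integer_,
                    stringsAsFactors = FALSE)
  for (chr in unique(chroms)) {
    gsub <- genes[genes$chrom == chr, , drop = FALSE]
    if (!nrow(gsub)) next
    # order by (tss, gene_id); for duplicated TSS keep the lowest gene_id
    gsub <- gsub[order(gsub$tss, gsub$gene_id), , drop = FALSE]
    gsub <- gsub[!duplicated(gsub$tss), , drop = FALSE]
    pidx <- which(chroms == chr)
    ci <- centers[pidx]
    lo <- findInterval(ci, gsub$tss)
    hi <- pmin(lo + 1L, nrow(gsub))
    lo <- pmax(lo, 1L)
    dlo <- abs(ci - gsub$tss[lo])
    dhi <- abs(ci - gsub$tss[hi])
    pick_hi <- dhi < dlo |
      (dhi == dlo & gsub$gene_id[hi] < gsub$gene_id[lo])
    sel <- ifelse(pick_hi, hi, lo)
    tss <- gsub$tss[sel]
    strand <- gsub$strand[sel]
    out$gene_id[pidx] <- gsub$gene_id[sel]
    out$distance[pidx] <- as.integer(ifelse(strand == "+", tss - ci, ci - tss))
  }
  out
}

#' Histogram of peak counts by signed distance to the nearest TSS
#'
#' @param peaks GRanges.
#' @param genes annotation.
#' @param bins bin edges in bp (signed, strand-oriented distance). Distances
#'   outside the edges fall into open-ended flanking bins; unassigned peaks
#'   (chromosome missing from the annotation) are counted in an
#'   `"unassigned"` row. Counts always sum to the number of peaks.
#' @return list with `assignments` (from [assign_nearest_tss()]) and
#'   `histogram` (`bin`, `lower`, `upper`, `count`).
#' @export
tss_distance_profile <- function(peaks, genes, bins = seq(-1e5, 1e5, by = 5000)) {
  asg <- assign_nearest_tss(peaks, genes)
  edges <- c(-Inf, sort(bins), Inf)
  d <- asg$distance[!is.na(asg$distance)]
  cuts <- cut(d, breaks = edges, right = FALSE)
  counts <- as.integer(table(cuts))
  hist <- data.frame(
    bin = levels(cuts),
    lower = edges[-length(edges)], upper = edges[-1],
    count = counts, stringsAsFactors = FALSE
  )
  hist <- rbind(hist, data.frame(bin = "unassigned", lower = NA, upper = NA,
                                 count = sum(is.na(asg$distance))))
  list(assignments = asg, histogram = hist)
}

#' Peak density enrichment around TSSs
#'
#' Ratio of peak-center density (peaks per bp) inside the merged +/- window
#' around all TSSs to the density outside, the quantity behind the
#' "about 5-fold higher within 5 kb of the TSS" profile.
#'
#' @param peaks GRanges.
#' @param genes annotation.
#' @param window half-width in bp (default 5000).
#' @param genome named vector of chromosome lengths (bp).
#' @return the density ratio (inside / outside).
#' @export
tss_enrichment_ratio <- function(peaks, genes, window = 5000, genome) {
  win <- GenomicRanges::reduce(GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$tss - window, 0) + 1,
                     pmin(genes$tss + window, genome[genes$chrom] - 1) + 1)
  ))
  centers <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                    IRanges::IRanges(peak_center0(peaks) + 1, width = 1))
  inside <- sum(IRanges::overlapsAny(centers, win))
  outside <- length(peaks) - inside
  w_in <- sum(GenomicRanges::width(win))
  w_out <- sum(genome) - w_in
  (inside / w_in) / (outside / w_out)
}

#' Annotate peaks by genomic feature
#'
#' Classifies each peak center as `promoter`, `gene_body` or `intergenic`
#' with precedence promoter > gene_body. The promoter is
#' `[TSS - upstream, TSS + downstream)` in the gene's orientation (0-based
#' half-open, mirrored for `-` genes).
#'
#' @param peaks GRanges.
#' @param genes annotation.
#' @param promoter_up,promoter_down promoter extent in bp (positive).
#' @return character vector of features, one per peak.
#' @export
annotate_regions <- function(peaks, genes, promoter_up = 2000, promoter_down = 500) {
  if (promoter_up <= 0 || promoter_down <= 0) stop("promoter extents must be positive")
  centers <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                    IRanges::IRanges(peak_center0(peaks) + 1, width = 1))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1, genes$end),
                                     strand = genes$strand)
  prom <- GenomicRanges::promoters(gr_genes, upstream = promoter_up,
                                   downstream = promoter_down)
  prom <- GenomicRanges::trim(prom)
  feature <- rep("intergenic", length(peaks))
  in_body <- IRanges::overlapsAny(centers, gr_genes, ignore.strand = TRUE)
  feature[in_body] <- "gene_body"
  in_prom <- IRanges::overlapsAny(centers, prom, ignore.strand = TRUE)
  feature[in_prom] <- "promoter"
  feature
}

#' Differential binding on per-peak counts
#'
#' Reuses the NB Wald engine on a peaks x ChIP-samples count matrix.
#'
#' @param peak_counts peaks x samples matrix (rownames = peak ids).
#' @param design ChIP sample sheet.
#' @param contrast a [contrast_spec()].
#' @param fdr significance cutoff on `padj`.
#' @param trend_weight dispersion shrinkage weight.
#' @return list with `results` (full per-peak DE table, gene_id column
#'   holding peak ids) and `significant` (subset with `padj < fdr` plus a
#'   `direction` column: `up` = more occupancy in the numerator).
#' @export
differential_binding <- function(peak_counts, design, contrast, fdr = 0.05,
                                 trend_weight = 0.5) {
  sf <- compute_size_factors(peak_counts)
  disp <- estimate_dispersions(peak_counts, sf, design, trend_weight = trend_weight)
  res <- wald_test(peak_counts, sf, disp, design, contrast)
  sig <- res[!is.na(res$padj) & res$padj < fdr, , drop = FALSE]
  sig$direction <- ifelse(sig$log2FoldChange >= 0, "up", "down")
  list(results = res, significant = sig)
}

#' Integrate differential binding with the regulation taxonomy
#'
#' Assigns each differential peak to its nearest TSS within `window` bp and
#' joins the regulation category of the target gene. The uncoupling summary
#' reports the fraction of differential peaks associated with
#' wild-type-regulated genes and, among those, the fractions per category;
#' "attenuated" combines `LOST`, `HYPO` and `INTERMEDIATE_LOW`.
#'
#' @param db_peaks GRanges of significant differential peaks with metadata
#'   columns `db_log2fc` and `db_fdr` (see [differential_binding()]).
#' @param genes annotation.
#' @param taxonomy table from [classify_mutant_effect()] for the matching
#'   cell-line pair.
#' @param window association window in bp (default 50 kb).
#' @return list with `records` (peak_id, gene_id, signed distance, db
#'   statistics, regulation_category) and `summary` (named list of counts
#'   and fractions).
#' @export
integrate_expression <- function(db_peaks, genes, taxonomy, window = 5e4) {
  if (is.null(taxonomy) || !nrow(taxonomy)) stop("taxonomy table is empty")
  if (!length(db_peaks)) {
    return(list(
      records = data.frame(peak_id = character(), gene_id = character(),
                           signed_distance = integer(), db_log2fc = numeric(),
                           db_fdr = numeric(), regulation_category = character()),
      summary = list(n_differential = 0L, n_associated = 0L,
                     frac_associated = 0, frac_attenuated = 0, frac_lost = 0,
                     frac_diminished = 0, frac_other = 0)
    ))
  }
  asg <- assign_nearest_tss(db_peaks, genes)
  asg$gene_id[!is.na(asg$distance) & abs(asg$distance) > window] <- NA
  asg$distance[is.na(asg$gene_id)] <- NA
  rec <- data.frame(
    peak_id = S4Vectors::mcols(db_peaks)$peak_id,
    gene_id = asg$gene_id,
    signed_distance = asg$distance,
    db_log2fc = S4Vectors::mcols(db_peaks)$db_log2fc,
    db_fdr = S4Vectors::mcols(db_peaks)$db_fdr,
    stringsAsFactors = FALSE
  )
  rec$regulation_category <- taxonomy$category[match(rec$gene_id, taxonomy$gene_id)]

  assoc <- !is.na(rec$regulation_category)
  n <- nrow(rec)
  na <- sum(assoc)
  attenu <- c("LOST", "HYPO", "INTERMEDIATE_LOW")
  summary <- list(
    n_differential = n,
    n_associated = na,
    frac_associated = na / n,
    frac_attenuated = if (na) sum(rec$regulation_category[assoc] %in% attenu) / na else 0,
    frac_lost = if (na) sum(rec$regulation_category[assoc] == "LOST") / na else 0,
    frac_diminished = if (na) {
      sum(rec$regulation_category[assoc] %in% c("HYPO", "INTERMEDIATE_LOW")) / na
    } else 0,
    frac_other = if (na) sum(!(rec$regulation_category[assoc] %in% attenu)) / na else 0
  )
  list(records = rec, summary = summary)
}

#' ChIP-qPCR fold enrichment by the comparative Ct method
#'
#' Percent input per condition is
#' `100 * 2^((Ct_input - log2(1 / input_fraction)) - Ct_IP)`; the fold
#' enrichment is the treated percent input over the vehicle percent input.
#'
#' @param ct_ip_treated,ct_input_treated,ct_ip_vehicle,ct_input_vehicle
#'   cycle-threshold values.
#' @param input_fraction fraction of lysate reserved as input (in (0, 1]).
#' @return list `percent_input_treated`, `percent_input_vehicle`,
#'   `fold_enrichment`.
#' @export
qpcr_enrichment <- function(ct_ip_treated, ct_input_treated,
                            ct_ip_vehicle, ct_input_vehicle,
                            input_fraction = 0.01) {
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("input_fraction must lie in (0, 1]")
  }
  cts <- c(ct_ip_treated, ct_input_treated, ct_ip_vehicle, ct_input_vehicle)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  adj <- log2(1 / input_fraction)
  pct_t <- 100 * 2^((ct_input_treated - adj) - ct_ip_treated)
  pct_v <- 100 * 2^((ct_input_vehicle - adj) - ct_ip_vehicle)
  list(percent_input_treated = pct_t, percent_input_vehicle = pct_v,
       fold_enrichment = pct_t / pct_v)
}
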