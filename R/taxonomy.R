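# Mutant-vs-wild-type regulation taxonomy and ligand-independent calling.

#' Threshold scheme for regulation calls
#'
#' Defaults encode the study's convention: genes are regulated at
#' `padj < 0.05`; a mutant "loses" a gene at `padj > 0.1`; hypo/hyper means
#' the mutant log2 fold change falls more than 20% below/above the wild-type
#' value; the unaffected band is within 10%. The relaxed ligand-independent
#' tier uses raw `p < 0.01`.
#'
#' @param alpha_regulated padj cutoff for "regulated".
#' @param alpha_lost padj cutoff above which mutant regulation is lost.
#' @param relaxed_p raw p cutoff of the relaxed ligand-independent tier.
#' @param hypo_ratio,hyper_ratio 20% band edges on the lfc ratio.
#' @param unaffected_band 10% band (inside the 20% band).
#' @return validated list of class `praf1_thresholds`.
#' @export
default_thresholds <- function(alpha_regulated = 0.05, alpha_lost = 0.1,
                               relaxed_p = 0.01, hypo_ratio = 0.8,
                               hyper_ratio = 1.2, unaffected_band = c(0.9, 1.1)) {
  if (!(alpha_regulated > 0 && alpha_regulated <= alpha_lost && alpha_lost < 1)) {
    stop("need 0 < alpha_regulated <= alpha_lost < 1")
  }
  if (!(hypo_ratio < 1 && hyper_ratio > 1)) stop("need hypo_ratio < 1 < hyper_ratio")
  if (!(unaffected_band[1] > hypo_ratio && unaffected_band[2] < hyper_ratio &&
        unaffected_band[1] < 1 && unaffected_band[2] > 1)) {
    stop("unaffected_band must lie inside (hypo_ratio, hyper_ratio) around 1")
  }
  structure(list(alpha_regulated = alpha_regulated, alpha_lost = alpha_lost,
                 relaxed_p = relaxed_p, hypo_ratio = hypo_ratio,
                 hyper_ratio = hyper_ratio, unaffected_band = unaffected_band),
            class = "praf1_thresholds")
}

#' Regulated gene set
#'
#' Genes with `padj < alpha` (strict inequality), in stable gene_id order.
#'
#' @param de DE result table.
#' @param alpha adjusted-p cutoff.
#' @return character vector of gene ids.
#' @export
call_regulated <- function(de, alpha = 0.05) {
  sort(de$gene_id[!is.na(de$padj) & de$padj < alpha])
}

#' Classify mutant behaviour of wild-type-regulated genes
#'
#' For every gene regulated in the wild-type contrast
#' (`padj_wt < alpha_regulated`), the decision ladder is:
#' \enumerate{
#'   \item `padj_mut > alpha_lost` (or untestable) => `LOST`;
#'   \item strictly opposite signs of the two log2 fold changes => `OPPOSITE`;
#'   \item otherwise the ratio `r = lfc_mut / lfc_wt` is banded:
#'     `r < 0.8` => `HYPO`; `0.8 <= r < 0.9` => `INTERMEDIATE_LOW`;
#'     `0.9 <= r <= 1.1` => `UNAFFECTED`; `1.1 < r <= 1.2` =>
#'     `INTERMEDIATE_HIGH`; `r > 1.2` => `HYPER`.
#' }
#' Ratios are ratios of log2 fold changes (the study's own worked comparison
#' is on the log2 scale). A mutant lfc of exactly 0 gives ratio 0 and hence
#' `HYPO` (attenuation to nothing); `OPPOSITE` requires a strict sign flip.
#' A wild-type lfc of exactly 0 (possible only at the pseudo-mean floor) is
#' flagged `AMBIGUOUS`.
#'
#' The partition is exhaustive by construction: every wild-type-regulated
#' gene receives exactly one category.
#'
#' @param wt,mut DE result tables for the wild-type and mutant contrasts
#'   (same genes).
#' @param th thresholds from [default_thresholds()].
#' @return data.frame `gene_id`, `category`, `lfc_wt`, `lfc_mut`, `ratio`,
#'   `padj_wt`, `padj_mut`.
#' @export
classify_mutant_effect <- function(wt, mut, th = default_thresholds()) {
  m <- merge(
    data.frame(gene_id = wt$gene_id, lfc_wt = wt$log2FoldChange, padj_wt = wt$padj),
    data.frame(gene_id = mut$gene_id, lfc_mut = mut$log2FoldChange, padj_mut = mut$padj),
    by = "gene_id"
  )
  m <- m[!is.na(m$padj_wt) & m$padj_wt < th$alpha_regulated, , drop = FALSE]
  m <- m[order(m$gene_id), , drop = FALSE]
  ratio <- ifelse(m$lfc_wt != 0, m$lfc_mut / m$lfc_wt, NA_real_)

  cat <- character(nrow(m))
  lost <- is.na(m$padj_mut) | m$padj_mut > th$alpha_lost
  ambiguous <- !lost & m$lfc_wt == 0
  opp <- !lost & !ambiguous & (m$lfc_wt * m$lfc_mut < 0)
  band <- !lost & !ambiguous & !opp
  cat[lost] <- "LOST"
  cat[ambiguous] <- "AMBIGUOUS"
  cat[opp] <- "OPPOSITE"
  r <- ratio[band]
  cat[band] <- ifelse(r < th$hypo_ratio, "HYPO",
               ifelse(r < th$unaffected_band[1], "INTERMEDIATE_LOW",
               ifelse(r <= th$unaffected_band[2], "UNAFFECTED",
               ifelse(r <= th$hyper_ratio, "INTERMEDIATE_HIGH", "HYPER"))))
  data.frame(gene_id = m$gene_id, category = cat, lfc_wt = m$lfc_wt,
             lfc_mut = m$lfc_mut, ratio = ratio, padj_wt = m$padj_wt,
             padj_mut = m$padj_mut, row.names = NULL, stringsAsFactors = FALSE)
}

#' Genes gained by a mutant
#'
#' Genes significant in the mutant contrast but not in the wild type
#' (`padj_mut < alpha_regulated`, `padj_wt >= alpha_regulated` or
#' untestable).
#'
#' @inheritParams classify_mutant_effect
#' @return data.frame `gene_id`, `lfc_wt`, `lfc_mut`, `padj_wt`, `padj_mut`,
#'   `category = "GAINED"`.
#' @export
call_gained <- function(wt, mut, th = default_thresholds()) {
  m <- merge(
    data.frame(gene_id = wt$gene_id, lfc_wt = wt$log2FoldChange, padj_wt = wt$padj),
    data.frame(gene_id = mut$gene_id, lfc_mut = mut$log2FoldChange, padj_mut = mut$padj),
    by = "gene_id"
  )
  keep <- !is.na(m$padj_mut) & m$padj_mut < th$alpha_regulated &
    (is.na(m$padj_wt) | m$padj_wt >= th$alpha_regulated)
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$gene_id), , drop = FALSE]
  data.frame(gene_id = m$gene_id, category = rep("GAINED", nrow(m)),
             lfc_wt = m$lfc_wt,
             lfc_mut = m$lfc_mut, padj_wt = m$padj_wt, padj_mut = m$padj_mut,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ligand-independent regulation tiers
#'
#' Operates on the PR-vs-empty-vector contrast under vehicle treatment.
#' `STRICT` uses `padj < alpha_regulated`; `RELAXED` uses raw
#' `p < relaxed_p`. The strict tier nests inside the relaxed tier whenever
#' the BH significance threshold lies below `relaxed_p`, i.e. whenever
#' fewer than `relaxed_p / alpha_regulated` (20% at the defaults) of the
#' tested genes are significant -- always the case for the sparse unliganded
#' contrast this tier structure is designed for.
#'
#' @param de DE result for the vehicle-treated PR-vs-EV contrast.
#' @param th thresholds.
#' @param tier `"STRICT"` or `"RELAXED"`.
#' @return data.frame `gene_id`, `direction` (`up`/`down`), `log2FoldChange`,
#'   `pvalue`, `padj`.
#' @export
call_ligand_independent <- function(de, th = default_thresholds(),
                                    tier = c("STRICT", "RELAXED")) {
  tier <- match.arg(tier)
  ctr <- attr(de, "contrast")
  if (!is.null(ctr) && (is.null(ctr$treatment) || ctr$treatment != "VEH")) {
    stop("ligand-independent calling requires a vehicle/vehicle cell-line contrast")
  }
  keep <- if (tier == "STRICT") {
    !is.na(de$padj) & de$padj < th$alpha_regulated
  } else {
    !is.na(de$pvalue) & de$pvalue < th$relaxed_p
  }
  out <- de[keep, c("gene_id", "log2FoldChange", "pvalue", "padj")]
  out <- out[order(out$gene_id), , drop = FALSE]
  out$direction <- ifelse(out$log2FoldChange >= 0, "up", "down")
  out[, c("gene_id", "direction", "log2FoldChange", "pvalue", "padj")]
}

#' Summarize taxonomy categories
#'
#' @param calls table from [classify_mutant_effect()].
#' @return data.frame of category counts and fractions of the regulated set.
#' @export
summarize_taxonomy <- function(calls) {
  levels <- c("LOST", "HYPO", "INTERMEDIATE_LOW", "UNAFFECTED",
              "INTERMEDIATE_HIGH", "HYPER", "OPPOSITE", "AMBIGUOUS")
  n <- vapply(levels, function(l) sum(calls$category == l), integer(1))
  data.frame(category = levels, count = n,
             fraction = if (nrow(calls)) n / nrow(calls) else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
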