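# Estrogen-progestin interplay: synergy, antagonism, and unliganded-PR
# modulation of the estrogen response.

#' Synergy calls for combined estrogen + progestin treatment
#'
#' A gene is `SYNERGY` iff the combined treatment is significantly different
#' from vehicle, from E2 alone and from R5020 alone
#' (`padj < alpha_regulated` in each of the three contrasts), the combined
#' magnitude exceeds both single-agent magnitudes by more than 20%
#' (`|lfc_combo| > hyper_ratio * max(|lfc_e2|, |lfc_r|)`), and the combined
#' effect has the same sign as the larger-magnitude single agent. "Greater
#' by 20% than either agent alone" is read against the stronger agent (max
#' rule): synergy conventionally means exceeding the best single agent.
#'
#' @param combo_vs_veh,combo_vs_e2,combo_vs_r DE results of the combined
#'   arm against vehicle, E2 alone, and R5020 alone (same cell line).
#' @param e2_vs_veh,r_vs_veh single-agent DE results against vehicle.
#' @param th thresholds from [default_thresholds()].
#' @return data.frame `gene_id`, `call` (`SYNERGY`/`NONE`), `lfc_e2`,
#'   `lfc_r`, `lfc_combo`, `padj_combo_veh`, `padj_combo_e2`,
#'   `padj_combo_r`.
#' @export
classify_synergy <- function(combo_vs_veh, combo_vs_e2, combo_vs_r,
                             e2_vs_veh, r_vs_veh, th = default_thresholds()) {
  tabs <- list(cv = combo_vs_veh, ce = combo_vs_e2, cr = combo_vs_r,
               e2 = e2_vs_veh, r = r_vs_veh)
  g <- tabs$cv$gene_id
  for (t in tabs) {
    if (!identical(sort(t$gene_id), sort(g))) stop("contrast tables must cover the same genes")
  }
  align <- function(t) t[match(g, t$gene_id), ]
  cv <- align(tabs$cv); ce <- align(tabs$ce); cr <- align(tabs$cr)
  e2 <- align(tabs$e2); r <- align(tabs$r)

  sig <- !is.na(cv$padj) & cv$padj < th$alpha_regulated &
    !is.na(ce$padj) & ce$padj < th$alpha_regulated &
    !is.na(cr$padj) & cr$padj < th$alpha_regulated
  single_max <- pmax(abs(e2$log2FoldChange), abs(r$log2FoldChange))
  lead_sign <- ifelse(abs(e2$log2FoldChange) >= abs(r$log2FoldChange),
                      sign(e2$log2FoldChange), sign(r$log2FoldChange))
  magn <- abs(cv$log2FoldChange) > th$hyper_ratio * single_max
  same <- sign(cv$log2FoldChange) == lead_sign

  out <- data.frame(
    gene_id = g,
    call = ifelse(sig & magn & same, "SYNERGY", "NONE"),
    lfc_e2 = e2$log2FoldChange, lfc_r = r$log2FoldChange,
    lfc_combo = cv$log2FoldChange,
    padj_combo_veh = cv$padj, padj_combo_e2 = ce$padj, padj_combo_r = cr$padj,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$gene_id), , drop = FALSE]
}

#' Antagonism calls for progestin action on estrogen-regulated genes
#'
#' Applies to E2-regulated genes (`padj_e2 < alpha_regulated`); both fold
#' changes are anchored at vehicle. `ANTAG_REVERSED` when the combined
#' effect flips sign relative to E2 alone (a combined lfc of exactly 0,
#' possible at the pseudo-mean floor, counts as reversed: the E2 effect is
#' gone entirely); `ANTAG_ATTENUATED` when the same-signed combined
#' magnitude falls below 80% of the E2 magnitude; otherwise `NONE`.
#'
#' @param e2_vs_veh,combo_vs_veh DE results (same cell line).
#' @param th thresholds.
#' @return data.frame `gene_id`, `call`, `lfc_e2`, `lfc_combo`, `padj_e2`,
#'   `padj_combo`, covering only E2-regulated genes.
#' @export
classify_antagonism <- function(e2_vs_veh, combo_vs_veh, th = default_thresholds()) {
  m <- merge(
    data.frame(gene_id = e2_vs_veh$gene_id, lfc_e2 = e2_vs_veh$log2FoldChange,
               padj_e2 = e2_vs_veh$padj),
    data.frame(gene_id = combo_vs_veh$gene_id, lfc_combo = combo_vs_veh$log2FoldChange,
               padj_combo = combo_vs_veh$padj),
    by = "gene_id"
  )
  m <- m[!is.na(m$padj_e2) & m$padj_e2 < th$alpha_regulated, , drop = FALSE]
  m <- m[order(m$gene_id), , drop = FALSE]
  reversed <- m$lfc_e2 * m$lfc_combo <= 0
  atten <- !reversed & abs(m$lfc_combo) < th$hypo_ratio * abs(m$lfc_e2)
  m$call <- ifelse(reversed, "ANTAG_REVERSED",
            ifelse(atten, "ANTAG_ATTENUATED", "NONE"))
  m[, c("gene_id", "call", "lfc_e2", "lfc_combo", "padj_e2", "padj_combo")]
}

#' Combined interplay classification
#'
#' One call per gene with documented precedence: synergy conditions are
#' evaluated first; genes not called `SYNERGY` are then assessed for
#' antagonism (E2-regulated genes only); everything else is `NONE`. The
#' precedence matters only for genes whose two single-agent effects have
#' opposite signs, where a combined effect can simultaneously exceed the
#' stronger agent and reverse the weaker one.
#'
#' @inheritParams classify_synergy
#' @return data.frame `gene_id`, `call` in
#'   `{SYNERGY, ANTAG_ATTENUATED, ANTAG_REVERSED, NONE}` plus the supporting
#'   lfc columns.
#' @export
classify_interplay <- function(combo_vs_veh, combo_vs_e2, combo_vs_r,
                               e2_vs_veh, r_vs_veh, th = default_thresholds()) {
  syn <- classify_synergy(combo_vs_veh, combo_vs_e2, combo_vs_r,
                          e2_vs_veh, r_vs_veh, th)
  ant <- classify_antagonism(e2_vs_veh, combo_vs_veh, th)
  call <- syn$call
  ai <- match(syn$gene_id, ant$gene_id)
  replace <- call == "NONE" & !is.na(ai) & ant$call[ai] != "NONE"
  call[replace] <- ant$call[ai[replace]]
  out <- syn
  out$call <- call
  out
}

#' Unliganded-PR modulation of the estrogen response
#'
#' For genes E2-regulated in the empty-vector line, compares the E2 log2
#' fold change in the PR-expressing line with the EV value:
#' `q = lfc_PRB / lfc_EV`. Same-signed `q < 0.8` => `REPRESSED`; `q > 1.2`
#' => `ENHANCED`; otherwise `NEUTRAL`. Opposite signs are maximal
#' attenuation => `REPRESSED`. An EV lfc of exactly 0 (pseudo-floor) is
#' flagged `AMBIGUOUS`.
#'
#' @param e2_in_ev,e2_in_pr E2-vs-vehicle DE results in the EV and
#'   PR-expressing lines.
#' @param th thresholds.
#' @return data.frame `gene_id`, `flag`, `lfc_ev`, `lfc_pr`, `ratio`,
#'   `padj_ev`.
#' @export
assess_e2_modulation <- function(e2_in_ev, e2_in_pr, th = default_thresholds()) {
  m <- merge(
    data.frame(gene_id = e2_in_ev$gene_id, lfc_ev = e2_in_ev$log2FoldChange,
               padj_ev = e2_in_ev$padj),
    data.frame(gene_id = e2_in_pr$gene_id, lfc_pr = e2_in_pr$log2FoldChange),
    by = "gene_id"
  )
  m <- m[!is.na(m$padj_ev) & m$padj_ev < th$alpha_regulated, , drop = FALSE]
  m <- m[order(m$gene_id), , drop = FALSE]
  m$ratio <- ifelse(m$lfc_ev != 0, m$lfc_pr / m$lfc_ev, NA_real_)
  m$flag <- ifelse(m$lfc_ev == 0, "AMBIGUOUS",
            ifelse(m$lfc_ev * m$lfc_pr < 0, "REPRESSED",
            ifelse(m$ratio < th$hypo_ratio, "REPRESSED",
            ifelse(m$ratio > th$hyper_ratio, "ENHANCED", "NEUTRAL"))))
  m[, c("gene_id", "flag", "lfc_ev", "lfc_pr", "ratio", "padj_ev")]
}
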