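#!/usr/bin/env Rscript
# Stage 3 — mutant regulation taxonomy and ligand-independent calling.
#
# Classifies every wild-type progestin-regulated gene by its behaviour in
# the FFF (hypoactive) and QQQ (hyperactive) AF1 mutants, lists genes
# gained by QQQ, and calls unliganded PR-B regulation at the strict
# (padj < 0.05) and relaxed (raw p < 0.01) tiers.

suppressMessages(library(praf1))

de <- function(nm) utils::read.delim(file.path("results/de", paste0(nm, ".tsv")))
dir.create("results/taxonomy", showWarnings = FALSE, recursive = TRUE)
th <- default_thresholds()

wt <- de("wt_r5020")
for (mut in c("fff", "qqq")) {
  calls <- classify_mutant_effect(wt, de(paste0(mut, "_r5020")), th)
  utils::write.table(calls, file.path("results/taxonomy", paste0(mut, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- summarize_taxonomy(calls)
  utils::write.table(sm, file.path("results/taxonomy", paste0(mut, "_summary.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(toupper(mut), ": ", nrow(calls), " wild-type-regulated genes")
  print(sm[sm$count > 0, ])
}

gained <- call_gained(wt, de("qqq_r5020"), th)
utils::write.table(gained, "results/taxonomy/qqq_gained.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("gained by QQQ: ", nrow(gained), " genes")

li <- de("li")
for (tier in c("STRICT", "RELAXED")) {
  calls <- call_ligand_independent(li, th, tier)
  utils::write.table(calls,
                     file.path("results/taxonomy",
                               paste0("ligand_independent_", tolower(tier), ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("ligand-independent (", tier, "): ", nrow(calls), " genes (",
          sum(calls$direction == "up"), " up)")
}
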