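#!/usr/bin/env Rscript
# Stage 4 — estrogen-progestin interplay in PR-B cells.
#
# Calls synergy (combined response significantly different from vehicle and
# from each single agent, and >20% larger than the stronger agent),
# antagonism (combined response >20% below the E2 response or sign-
# reversed), and unliganded-PR modulation of the estrogen response
# (EV vs PR-B fold-change comparison).

suppressMessages(library(praf1))

de <- function(nm) utils::read.delim(file.path("results/de", paste0(nm, ".tsv")))
dir.create("results/interplay", showWarnings = FALSE, recursive = TRUE)
th <- default_thresholds()

ip <- classify_interplay(de("wt_combo"), de("wt_combo_vs_e2"),
                         de("wt_combo_vs_r"), de("wt_e2"), de("wt_r5020"), th)
utils::write.table(ip, "results/interplay/calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("interplay calls:")
print(table(ip$call))

e2mod <- assess_e2_modulation(de("ev_e2"), de("wt_e2"), th)
utils::write.table(e2mod, "results/interplay/e2_modulation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("unliganded modulation of the E2 response (E2-regulated genes in EV):")
print(table(e2mod$flag))
message(sprintf("repressed fraction: %.1f%%",
                100 * mean(e2mod$flag == "REPRESSED")))
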