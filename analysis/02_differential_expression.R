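#!/usr/bin/env Rscript
# Stage 2 — negative-binomial Wald contrasts over the factorial.
#
# Normalizes by median-of-ratios, estimates MoM dispersions with trend
# shrinkage, and runs every contrast the downstream classifiers need:
# progestin response per PR line, estrogen response in EV and PR-B,
# combined-arm contrasts, and the unliganded PR-B vs EV vehicle contrast.

suppressMessages(library(praf1))

rna <- read_counts("results/data/rna_counts.tsv", "results/data/rna_design.tsv")
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

sf <- compute_size_factors(rna$counts)
disp <- estimate_dispersions(rna$counts, sf, rna$design)
message("size factors in [", round(min(sf), 3), ", ", round(max(sf), 3), "]; ",
        "median dispersion ", signif(median(disp$disp), 3))

contrasts <- list(
  wt_r5020 = contrast_spec("R5020", "VEH", cell_line = "WT"),
  fff_r5020 = contrast_spec("R5020", "VEH", cell_line = "FFF"),
  qqq_r5020 = contrast_spec("R5020", "VEH", cell_line = "QQQ"),
  ev_e2 = contrast_spec("E2", "VEH", cell_line = "EV"),
  wt_e2 = contrast_spec("E2", "VEH", cell_line = "WT"),
  wt_combo = contrast_spec("E2R", "VEH", cell_line = "WT"),
  wt_combo_vs_e2 = contrast_spec("E2R", "E2", cell_line = "WT"),
  wt_combo_vs_r = contrast_spec("E2R", "R5020", cell_line = "WT"),
  li = contrast_spec("WT", "EV", treatment = "VEH")
)
for (nm in names(contrasts)) {
  de <- wald_test(rna$counts, sf, disp, rna$design, contrasts[[nm]])
  write_de_result(de, file.path("results/de", paste0(nm, ".tsv")))
  message(sprintf("%-16s %4d genes at padj < 0.05", nm,
                  length(call_regulated(de, 0.05))))
}
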