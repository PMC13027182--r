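#!/usr/bin/env Rscript
# Stage 1 — simulate the factorial study with known ground truth.
#
# Generates 2000 genes across the eleven regulatory archetypes, duplicate
# RNA-Seq counts over the 4 cell-line x 4 treatment factorial, and
# triplicate ChIP-Seq peak sets / per-peak counts for wild type vs FFF
# under progestin. Everything downstream reads from results/data.

suppressMessages(library(praf1))

cfg <- default_pipeline_config(seed = 42)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

truth <- generate_truth(cfg$n_genes, cfg$archetype_fractions, cfg$effect,
                        seed = cfg$seed)
write_truth(truth, "results/data/truth.tsv")
message("truth table: ", nrow(truth), " genes; archetype counts:")
print(table(truth$archetype))

rna_design <- make_rna_design(n_rep = cfg$rna$n_rep)
rna <- simulate_expression_counts(truth, rna_design,
                                  library_size_spread = cfg$rna$library_size_spread,
                                  seed = cfg$seed)
write_counts(rna$counts, rna_design, "results/data/rna_counts.tsv",
             "results/data/rna_design.tsv")
message("RNA counts: ", nrow(rna$counts), " x ", ncol(rna$counts),
        " (median library ", median(colSums(rna$counts)), ")")

chip_design <- make_chip_design()
chip <- simulate_chip_data(truth, chip_design, genome = cfg$genome,
                           config = cfg$chip, seed = cfg$seed)
write_counts(chip$peak_counts, chip_design, "results/data/chip_counts.tsv",
             "results/data/chip_design.tsv")
write_gene_annotation(chip$annotation, "results/data/genes.bed")
for (nm in names(chip$replicate_peaks)) {
  write_peaks(chip$replicate_peaks[[nm]],
              file.path("results/data", paste0("peaks_", nm, ".bed")))
}
write_peaks(chip$latent_peaks, "results/data/peaks_latent.bed")
utils::write.table(chip$peak_truth, "results/data/peak_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("ChIP: ", length(chip$latent_peaks), " latent peaks, ",
        sum(chip$peak_truth$is_differential), " truly differential")
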