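# End-to-end orchestration: simulate -> DE -> taxonomy -> interplay ->
# ChIP integration, with replicate QC and a machine-readable report
# including truth-recovery rates.

#' Replicate correlation QC
#'
#' Pearson R^2 between log2(normalized count + 1) profiles for every
#' replicate pair within each condition; pairs below `floor` are flagged.
#' Conditions with a single replicate are skipped with a notice.
#'
#' @param counts genes x samples count matrix.
#' @param design sample sheet.
#' @param sf optional size factors (median-of-ratios by default).
#' @param floor flagging threshold on R^2 (default 0.95).
#' @return data.frame `condition`, `sample_a`, `sample_b`, `r_squared`,
#'   `flagged`.
#' @export
qc_replicate_correlation <- function(counts, design, sf = NULL, floor = 0.95) {
  if (is.null(sf)) sf <- compute_size_factors(counts)
  lognorm <- log2(sweep(counts, 2, sf, "/") + 1)
  out <- list()
  for (cond in unique(condition_key(design))) {
    idx <- which(condition_key(design) == cond)
    if (length(idx) < 2) {
      message("qc: condition ", cond, " has a single replicate; pair skipped")
      next
    }
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq((a + 1), length(idx))) {
        r2 <- stats::cor(lognorm[, idx[a]], lognorm[, idx[b]])^2
        out[[length(out) + 1]] <- data.frame(
          condition = cond,
          sample_a = design$sample_id[idx[a]], sample_b = design$sample_id[idx[b]],
          r_squared = r2, flagged = r2 < floor, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(condition = character(), sample_a = character(),
                      sample_b = character(), r_squared = numeric(),
                      flagged = logical()))
  }
  do.call(rbind, out)
}

#' Demo pipeline configuration
#'
#' The default simulation is a desk-scale image of the study design: 2000
#' genes over eleven archetypes, duplicate RNA-Seq over the full 4 x 4
#' factorial, triplicate ChIP-Seq for wild type and FFF under progestin,
#' and 200 latent peaks on a two-chromosome 20 Mb genome.
#'
#' @param seed master seed for every stochastic stage.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 42) {
  list(
    seed = seed,
    n_genes = 2000,
    archetype_fractions = c(
      "NULL" = 0.40, LIGAND_UP = 0.10, LIGAND_DOWN = 0.05,
      ATTENUATED_FFF = 0.10, HYPER_QQQ = 0.05,
      LIGAND_INDEP_UP = 0.04, LIGAND_INDEP_DOWN = 0.02,
      E2_ONLY = 0.10, SYNERGY = 0.05, ANTAG_ATTEN = 0.05,
      ANTAG_REVERSED = 0.04
    ),
    effect = effect_config(),
    rna = list(n_rep = 2, library_size_spread = 0.2),
    chip = chip_config(),
    genome = c(chr1 = 1e7, chr2 = 1e7),
    thresholds = default_thresholds(),
    consensus = list(min_support = 2, min_width = 50),
    promoter = c(up = 2000, down = 500),
    association_window = 5e4,
    qc_floor = 0.95
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the demo defaults; the `thresholds`,
#' `effect` and `chip` blocks are passed through their validating
#' constructors.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = user$seed %||% 42)
  for (k in setdiff(names(user), c("thresholds", "effect", "chip"))) cfg[[k]] <- user[[k]]
  if (!is.null(user$thresholds)) cfg$thresholds <- do.call(default_thresholds, user$thresholds)
  if (!is.null(user$effect)) cfg$effect <- do.call(effect_config, user$effect)
  if (!is.null(user$chip)) cfg$chip <- do.call(chip_config, user$chip)
  if (!is.null(user$archetype_fractions)) {
    cfg$archetype_fractions <- unlist(user$archetype_fractions)
  }
  if (!is.null(user$genome)) cfg$genome <- unlist(user$genome)
  validate_pipeline_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pipeline configuration before any stage runs
#'
#' @param config configuration list.
#' @return the config, invisibly; errors on the first violated invariant.
#' @export
validate_pipeline_config <- function(config) {
  need <- c("seed", "n_genes", "archetype_fractions", "effect", "rna", "chip",
            "genome", "thresholds", "consensus", "promoter",
            "association_window", "qc_floor")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing fields: ", paste(miss, collapse = ", "))
  if (config$n_genes < 1) stop("n_genes must be >= 1")
  if (abs(sum(config$archetype_fractions) - 1) > 1e-9) {
    stop("archetype_fractions must sum to 1")
  }
  if (!inherits(config$thresholds, "praf1_thresholds")) {
    config$thresholds <- do.call(default_thresholds, config$thresholds)
  }
  if (config$rna$n_rep < 2) stop("RNA design needs >= 2 replicates")
  if (config$consensus$min_support < 1) stop("min_support must be >= 1")
  invisible(config)
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("stage %-22s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline on simulated data
#'
#' Stages, in dependency order: ground truth and factorial RNA counts;
#' normalization, dispersion and the Wald contrasts (progestin response per
#' PR line, estrogen response in EV and PR lines, combined-arm contrasts,
#' and the vehicle PR-vs-EV contrast); regulation taxonomy for FFF and QQQ
#' plus gained genes; ligand-independent tiers; interplay and E2-modulation
#' calls; ChIP simulation, consensus peaks, TSS profile, feature annotation,
#' differential occupancy and expression integration; replicate QC; and
#' truth-recovery rates. All tables are written under `outdir` with a
#' manifest; identical config and seed reproduce identical outputs.
#'
#' @param config list from [default_pipeline_config()] /
#'   [read_pipeline_config()].
#' @param outdir output directory (created if needed); `NULL` skips writing.
#' @return the run report (nested list), invisibly when writing.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL) {
  validate_pipeline_config(config)
  th <- config$thresholds
  seed <- config$seed

  truth <- run_stage("simulate_truth", generate_truth(
    config$n_genes, config$archetype_fractions, config$effect, seed = seed))
  rna_design <- make_rna_design(n_rep = config$rna$n_rep)
  rna <- run_stage("simulate_rna", simulate_expression_counts(
    truth, rna_design, library_size_spread = config$rna$library_size_spread,
    seed = seed))

  sf <- run_stage("size_factors", compute_size_factors(rna$counts))
  disp <- run_stage("dispersions", estimate_dispersions(rna$counts, sf, rna_design))

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
  de <- run_stage("wald_contrasts", lapply(contrasts, function(ctr) {
    wald_test(rna$counts, sf, disp, rna_design, ctr)
  }))

  tax_fff <- run_stage("taxonomy_fff",
                       classify_mutant_effect(de$wt_r5020, de$fff_r5020, th))
  tax_qqq <- classify_mutant_effect(de$wt_r5020, de$qqq_r5020, th)
  gained_qqq <- call_gained(de$wt_r5020, de$qqq_r5020, th)

  li_strict <- call_ligand_independent(de$li, th, "STRICT")
  li_relaxed <- call_ligand_independent(de$li, th, "RELAXED")

  interplay <- run_stage("interplay", classify_interplay(
    de$wt_combo, de$wt_combo_vs_e2, de$wt_combo_vs_r, de$wt_e2, de$wt_r5020, th))
  e2mod <- assess_e2_modulation(de$ev_e2, de$wt_e2, th)

  chip_design <- make_chip_design()
  chip <- run_stage("simulate_chip", simulate_chip_data(
    truth, chip_design, genome = config$genome, config = config$chip, seed = seed))
  wt_reps <- chip$replicate_peaks[chip_design$cell_line == "WT"]
  consensus <- run_stage("consensus", build_consensus(
    wt_reps, min_support = config$consensus$min_support,
    min_width = config$consensus$min_width))
  profile <- tss_distance_profile(consensus, chip$annotation)
  enrich <- tss_enrichment_ratio(chip$latent_peaks, chip$annotation,
                                 window = config$chip$tss_window,
                                 genome = config$genome)
  features <- annotate_regions(consensus, chip$annotation,
                               promoter_up = config$promoter[["up"]],
                               promoter_down = config$promoter[["down"]])
  db <- run_stage("differential_binding", differential_binding(
    chip$peak_counts, chip_design,
    contrast_spec("FFF", "WT", treatment = "R5020"), fdr = th$alpha_regulated))
  db_up <- db$significant[db$significant$direction == "up", , drop = FALSE]
  db_peaks <- chip$latent_peaks[match(db_up$gene_id,
                                      S4Vectors::mcols(chip$latent_peaks)$peak_id)]
  S4Vectors::mcols(db_peaks)$db_log2fc <- db_up$log2FoldChange
  S4Vectors::mcols(db_peaks)$db_fdr <- db_up$padj
  integration <- run_stage("integration", integrate_expression(
    db_peaks, chip$annotation, tax_fff, window = config$association_window))

  qc <- run_stage("qc", qc_replicate_correlation(rna$counts, rna_design, sf,
                                                 floor = config$qc_floor))
  recovery <- run_stage("recovery", recovery_rates(
    truth, tax_fff, tax_qqq, li_relaxed, interplay))

  tax_sum_fff <- summarize_taxonomy(tax_fff)
  tax_sum_qqq <- summarize_taxonomy(tax_qqq)
  report <- list(
    schema_version = 1L,
    seed = seed,
    thresholds = unclass(th),
    n_genes = config$n_genes,
    de = lapply(de, function(d) {
      list(n_regulated = length(call_regulated(d, th$alpha_regulated)))
    }),
    taxonomy = list(
      fff = list(n_regulated_wt = nrow(tax_fff),
                 counts = stats::setNames(as.list(tax_sum_fff$count),
                                          tax_sum_fff$category)),
      qqq = list(n_regulated_wt = nrow(tax_qqq),
                 counts = stats::setNames(as.list(tax_sum_qqq$count),
                                          tax_sum_qqq$category),
                 n_gained = nrow(gained_qqq))
    ),
    ligand_independent = list(n_strict = nrow(li_strict),
                              n_relaxed = nrow(li_relaxed)),
    interplay = list(
      n_synergy = sum(interplay$call == "SYNERGY"),
      n_antag_attenuated = sum(interplay$call == "ANTAG_ATTENUATED"),
      n_antag_reversed = sum(interplay$call == "ANTAG_REVERSED"),
      n_e2_repressed = sum(e2mod$flag == "REPRESSED")
    ),
    chip = list(
      n_latent_peaks = length(chip$latent_peaks),
      n_consensus_peaks = length(consensus),
      tss_enrichment_ratio = enrich,
      features = as.list(table(features)),
      n_differential = nrow(db$significant),
      n_differential_up_in_fff = nrow(db_up),
      integration = integration$summary
    ),
    qc = list(n_pairs = nrow(qc), min_r_squared = min(qc$r_squared),
              n_flagged = sum(qc$flagged)),
    recovery = recovery
  )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_truth(truth, file.path(outdir, "truth.tsv"))
    write_counts(rna$counts, rna_design, file.path(outdir, "rna_counts.tsv"),
                 file.path(outdir, "rna_design.tsv"))
    for (nm in names(de)) {
      write_de_result(de[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")))
    }
    utils::write.table(tax_fff, file.path(outdir, "taxonomy_fff.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tax_qqq, file.path(outdir, "taxonomy_qqq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(interplay, file.path(outdir, "interplay.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(e2mod, file.path(outdir, "e2_modulation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_peaks(consensus, file.path(outdir, "consensus_peaks.bed"))
    write_gene_annotation(chip$annotation, file.path(outdir, "genes.bed"))
    utils::write.table(integration$records, file.path(outdir, "integration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(qc, file.path(outdir, "qc_replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

#' Per-archetype recovery rates against the ground truth
#'
#' Sensitivity of the downstream calls for the archetypes they are meant to
#' recover: attenuated genes called `HYPO` or `LOST` in the FFF taxonomy,
#' hyperactivated genes called `HYPER` or `INTERMEDIATE_HIGH` in the QQQ
#' taxonomy, null genes left uncalled, ligand-independent genes recovered in
#' the relaxed tier, and correct interplay calls.
#'
#' @param truth truth table.
#' @param tax_fff,tax_qqq taxonomy tables.
#' @param li_relaxed relaxed-tier ligand-independent calls.
#' @param interplay combined interplay calls.
#' @return named list of recovery rates in `[0, 1]` (NA when an archetype is
#'   absent).
#' @export
recovery_rates <- function(truth, tax_fff, tax_qqq, li_relaxed, interplay) {
  rate <- function(ids, called) if (length(ids)) mean(ids %in% called) else NA_real_
  att <- truth$gene_id[truth$archetype == "ATTENUATED_FFF"]
  hyp <- truth$gene_id[truth$archetype == "HYPER_QQQ"]
  nul <- truth$gene_id[truth$archetype == "NULL"]
  li <- truth$gene_id[truth$archetype %in% c("LIGAND_INDEP_UP", "LIGAND_INDEP_DOWN")]
  syn <- truth$gene_id[truth$archetype == "SYNERGY"]
  ant_a <- truth$gene_id[truth$archetype == "ANTAG_ATTEN"]
  ant_r <- truth$gene_id[truth$archetype == "ANTAG_REVERSED"]
  list(
    attenuated_called_hypo_or_lost = rate(
      att, tax_fff$gene_id[tax_fff$category %in% c("HYPO", "LOST")]),
    hyper_called_hyper_or_high = rate(
      hyp, tax_qqq$gene_id[tax_qqq$category %in% c("HYPER", "INTERMEDIATE_HIGH")]),
    null_uncalled_wt = if (length(nul)) {
      1 - mean(nul %in% tax_fff$gene_id)
    } else NA_real_,
    ligand_indep_relaxed = rate(li, li_relaxed$gene_id),
    synergy_called = rate(syn, interplay$gene_id[interplay$call == "SYNERGY"]),
    antag_atten_called = rate(
      ant_a, interplay$gene_id[interplay$call == "ANTAG_ATTENUATED"]),
    antag_reversed_called = rate(
      ant_r, interplay$gene_id[interplay$call == "ANTAG_REVERSED"])
  )
}
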