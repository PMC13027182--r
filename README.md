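# praf1 — progesterone receptor AF1 activity from factorial RNA-Seq and ChIP-Seq

Activation Function 1 (AF1) lives in the progesterone receptor's disordered
N-terminal domain; methylation-mimic substitutions at K464/K481/R492 make the
receptor hypoactive (KKR→FFF) or hyperactive (KKR→QQQ). `praf1` implements,
as a tested R package plus a numbered analysis workflow, the full inferential
chain for quantifying AF1-dependent receptor activity from a factorial design
of four MCF-7-derived cell lines (empty vector EV, wild-type PR-B, PR-B-FFF,
PR-B-QQQ) crossed with four treatments (vehicle, the progestin R5020,
estradiol E2, and E2+R5020):

- a self-contained **negative-binomial Wald engine**: median-of-ratios size
  factors, method-of-moments dispersions shrunk toward a fitted
  mean–dispersion trend, per-condition NB mean MLEs with delta-method
  standard errors, two-sided Wald p-values and Benjamini–Hochberg adjustment
  (counts `K ~ NB(s·q, α)`, `Var = μ + αμ²`);
- the **mutant regulation taxonomy** for wild-type-regulated genes
  (padj < 0.05): LOST (mutant padj > 0.1), OPPOSITE, and ratio bands on
  `r = lfc_mut / lfc_wt` — HYPO (r < 0.8), INTERMEDIATE_LOW [0.8, 0.9),
  UNAFFECTED [0.9, 1.1], INTERMEDIATE_HIGH (1.1, 1.2], HYPER (r > 1.2) —
  plus GAINED genes;
- **ligand-independent calling** on the vehicle PR-B-vs-EV contrast at a
  strict (padj < 0.05) and a relaxed (raw p < 0.01) tier;
- **estrogen–progestin interplay**: SYNERGY (combined arm significant vs
  vehicle and vs both single agents, magnitude > 1.2× the stronger agent,
  same sign), ANTAG_ATTENUATED (< 0.8× the E2 magnitude) and
  ANTAG_REVERSED (sign flip), plus unliganded-PR modulation of the E2
  response;
- **ChIP-Seq integration**: base-pair-majority consensus peaks from
  replicate peak sets, signed nearest-TSS distance profiles,
  promoter/gene-body/intergenic annotation, NB differential occupancy, the
  occupancy/transactivation uncoupling summary, and comparative-Ct
  ChIP-qPCR enrichment;
- a **seeded synthetic-data generator** emulating the study design
  (duplicate RNA-Seq, triplicate ChIP-Seq, eleven gene archetypes, 5-fold
  peak enrichment near TSSs) with a full ground-truth table, so every stage
  is validated by parameter recovery.

## Worked example

```r
library(praf1)

report <- run_pipeline(default_pipeline_config(seed = 42), outdir = "results/pipeline")
str(report$recovery)
```

With the demo configuration (2000 genes, duplicates, dispersion 0.05, 200
ChIP peaks, seed 42) this simulates the factorial, runs nine Wald
contrasts, classifies every gene, and prints the recovery of the known
ground truth:

```
List of 7
 $ attenuated_called_hypo_or_lost: num 0.945
 $ hyper_called_hyper_or_high    : num 0.96
 $ null_uncalled_wt              : num 0.97
 $ ligand_indep_relaxed          : num 0.992
 $ synergy_called                : num 0.52
 $ antag_atten_called            : num 0.89
 $ antag_reversed_called         : num 1
```

i.e. 94.5% of truly FFF-attenuated genes are called HYPO or LOST, 96% of
truly QQQ-hyperactivated genes HYPER or INTERMEDIATE_HIGH, 97% of null
genes stay uncalled, and 99% of constitutive unliganded targets appear in
the relaxed ligand-independent tier. (Synergy recovery is lower at
duplicate-level noise because the 20% margin is measured against the max of
two noisy single-agent estimates; the methods vignette quantifies this.)
The same run reports 812 / 768 / 809 progestin-regulated genes in the
wild-type / FFF / QQQ lines; among the 812 wild-type targets the FFF
taxonomy counts 56 LOST, 260 HYPO, 88 INTERMEDIATE_LOW, 213 UNAFFECTED,
88 INTERMEDIATE_HIGH and 107 HYPER; 122 strict / 130 relaxed
ligand-independent genes; 59 synergistic and 199 antagonistic genes; and on
the ChIP side 196 consensus peaks, 55 differential peaks (50 with greater
FFF occupancy) of which 96% lie within 50 kb of a wild-type-regulated gene
and 85% of those genes are attenuated — the occupancy/transactivation
uncoupling signature.

The numbered drivers under `analysis/` run the same chain step by step and
leave every intermediate table under `results/`:

```sh
Rscript analysis/01_simulate.R               # truth + RNA counts + ChIP data
Rscript analysis/02_differential_expression.R
Rscript analysis/03_regulation_taxonomy.R
Rscript analysis/04_hormone_interplay.R
Rscript analysis/05_chip_integration.R
Rscript analysis/06_qc_report.R              # replicate QC + report.json
```

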