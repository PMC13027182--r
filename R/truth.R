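# Ground-truth generator: gene archetypes and their expected log2 shifts
# across the 4 cell-line x 4 treatment factorial.

#' Gene archetypes understood by the simulator
#'
#' Each archetype fully determines the expected log2 mean shift of every
#' (cell line, treatment) cell relative to vehicle-treated EV:
#' \describe{
#'   \item{NULL}{no regulation anywhere.}
#'   \item{LIGAND_UP / LIGAND_DOWN}{progestin (R5020) response of fixed sign
#'     in all PR-expressing lines, unchanged by the AF1 mutants.}
#'   \item{ATTENUATED_FFF}{progestin response multiplied by
#'     `attenuation_factor` in the FFF line.}
#'   \item{HYPER_QQQ}{progestin response multiplied by `hyper_factor` in the
#'     QQQ line.}
#'   \item{LIGAND_INDEP_UP / LIGAND_INDEP_DOWN}{constitutive shift in every
#'     PR-expressing line under every treatment (unliganded receptor
#'     activity, visible in the PRB-vs-EV vehicle contrast).}
#'   \item{E2_ONLY}{estrogen response present in all lines (EV included); a
#'     configurable fraction carries an unliganded-PR attenuation of the E2
#'     response in PR-expressing lines.}
#'   \item{SYNERGY}{equal E2 and R5020 responses whose combination exceeds
#'     either single agent by `synergy_factor`.}
#'   \item{ANTAG_ATTEN}{E2 response blunted to `antag_factor` of itself under
#'     combined treatment.}
#'   \item{ANTAG_REVERSED}{E2 response reversed in sign under combined
#'     treatment (R5020 pushes the opposite way).}
#' }
#' @export
ARCHETYPES <- c(
  "NULL", "LIGAND_UP", "LIGAND_DOWN", "ATTENUATED_FFF", "HYPER_QQQ",
  "LIGAND_INDEP_UP", "LIGAND_INDEP_DOWN", "E2_ONLY",
  "SYNERGY", "ANTAG_ATTEN", "ANTAG_REVERSED"
)

#' Default effect-size configuration for the simulator
#'
#' Magnitudes are on the log2 scale. The per-gene |log2FC| is drawn uniformly
#' from `[lfc_min, lfc_max]`; the default 2--3 range is the scale of strongly
#' induced primary PR targets. Dispersion is the NB overdispersion
#' (variance = mu + dispersion * mu^2); base means are log-normal.
#'
#' @param lfc_min,lfc_max bounds of the |log2 fold change| draw.
#' @param attenuation_factor multiplier on the progestin response in FFF
#'   for `ATTENUATED_FFF` genes (in (0, 1]).
#' @param hyper_factor multiplier on the progestin response in QQQ for
#'   `HYPER_QQQ` genes (>= 1).
#' @param synergy_factor combined-over-single-agent magnitude ratio for
#'   `SYNERGY` genes.
#' @param antag_factor combined-over-E2 magnitude ratio for `ANTAG_ATTEN`.
#' @param reversed_r_factor,reversed_combo_factor R5020 and combined-response
#'   magnitudes (as fractions of the E2 magnitude, opposite sign) for
#'   `ANTAG_REVERSED` genes.
#' @param e2_mod_fraction fraction of `E2_ONLY` genes whose E2 response is
#'   attenuated by unliganded PR.
#' @param e2_mod_factor the attenuation multiplier applied to that fraction.
#' @param dispersion NB dispersion shared by all genes by default.
#' @param base_mean_meanlog,base_mean_sdlog,base_mean_min log-normal
#'   parameters and floor for expected base counts.
#' @return a named list, validated.
#' @export
effect_config <- function(lfc_min = 2, lfc_max = 3,
                          attenuation_factor = 0.5, hyper_factor = 1.5,
                          synergy_factor = 1.5, antag_factor = 0.6,
                          reversed_r_factor = 0.8, reversed_combo_factor = 0.4,
                          e2_mod_fraction = 0.1, e2_mod_factor = 0.5,
                          dispersion = 0.05,
                          base_mean_meanlog = log(200), base_mean_sdlog = 1.5,
                          base_mean_min = 10) {
  if (lfc_min <= 0 || lfc_max < lfc_min) stop("need 0 < lfc_min <= lfc_max")
  if (attenuation_factor <= 0 || attenuation_factor > 1) {
    stop("attenuation_factor must lie in (0, 1]")
  }
  if (hyper_factor < 1) stop("hyper_factor must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (base_mean_min <= 0) stop("base_mean_min must be > 0")
  if (e2_mod_fraction < 0 || e2_mod_fraction > 1) {
    stop("e2_mod_fraction must lie in [0, 1]")
  }
  as.list(environment())
}

#' Apportion gene counts to archetype proportions
#'
#' Largest-remainder rounding so the counts always sum to `n` exactly and
#' match the proportions to rounding.
#' @keywords internal
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a ground-truth gene table
#'
#' Draws one row per gene: archetype, expected base count, per-treatment log2
#' effects and the mutant multipliers. Each gene uses its own seeded RNG
#' substream, so regenerating with more genes reproduces the original rows.
#'
#' @param n_genes number of genes (>= 1).
#' @param archetype_fractions named numeric vector of archetype proportions
#'   summing to 1 (names from [ARCHETYPES]).
#' @param effect list from [effect_config()].
#' @param seed integer master seed.
#' @return a `data.frame` ("truth table") with one row per gene and columns
#'   `gene_id`, `archetype`, `base_mean`, `dispersion`, `lfc_r5020`,
#'   `lfc_e2`, `lfc_combo`, `lfc_li`, `atten_fff`, `hyper_qqq`, `e2_mod`.
#'   The `effect` list is attached as attribute `"effect"`.
#' @export
generate_truth <- function(n_genes, archetype_fractions, effect = effect_config(),
                           seed = 1) {
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be >= 1")
  n_genes <- as.integer(n_genes)
  fr <- unlist(archetype_fractions)
  if (is.null(names(fr)) || !all(names(fr) %in% ARCHETYPES)) {
    stop("archetype_fractions must be named by archetype: ",
         paste(ARCHETYPES, collapse = ", "))
  }
  if (abs(sum(fr) - 1) > 1e-9) stop("archetype_fractions must sum to 1")
  counts <- apportion(n_genes, fr)
  arch <- rep(names(fr), counts)

  n <- n_genes
  tt <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(n)),
    archetype = arch,
    base_mean = NA_real_, dispersion = effect$dispersion,
    lfc_r5020 = 0, lfc_e2 = 0, lfc_combo = 0, lfc_li = 0,
    atten_fff = 1, hyper_qqq = 1, e2_mod = 1,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    gs <- substream_seed(seed, i, salt = 1)
    draws <- withr::with_seed(gs, {
      list(
        base = max(effect$base_mean_min,
                   stats::rlnorm(1, effect$base_mean_meanlog, effect$base_mean_sdlog)),
        L = stats::runif(1, effect$lfc_min, effect$lfc_max),
        s = sample(c(-1, 1), 1),
        u = stats::runif(1)
      )
    })
    tt$base_mean[i] <- draws$base
    L <- draws$L
    s <- draws$s
    a <- arch[i]
    if (a == "LIGAND_UP") {
      tt$lfc_r5020[i] <- L; tt$lfc_combo[i] <- L
    } else if (a == "LIGAND_DOWN") {
      tt$lfc_r5020[i] <- -L; tt$lfc_combo[i] <- -L
    } else if (a == "ATTENUATED_FFF") {
      tt$lfc_r5020[i] <- s * L; tt$lfc_combo[i] <- s * L
      tt$atten_fff[i] <- effect$attenuation_factor
    } else if (a == "HYPER_QQQ") {
      tt$lfc_r5020[i] <- s * L; tt$lfc_combo[i] <- s * L
      tt$hyper_qqq[i] <- effect$hyper_factor
    } else if (a == "LIGAND_INDEP_UP") {
      tt$lfc_li[i] <- L
    } else if (a == "LIGAND_INDEP_DOWN") {
      tt$lfc_li[i] <- -L
    } else if (a == "E2_ONLY") {
      tt$lfc_e2[i] <- s * L; tt$lfc_combo[i] <- s * L
      if (draws$u < effect$e2_mod_fraction) tt$e2_mod[i] <- effect$e2_mod_factor
    } else if (a == "SYNERGY") {
      tt$lfc_e2[i] <- s * L; tt$lfc_r5020[i] <- s * L
      tt$lfc_combo[i] <- s * effect$synergy_factor * L
    } else if (a == "ANTAG_ATTEN") {
      tt$lfc_e2[i] <- s * L
      tt$lfc_combo[i] <- s * effect$antag_factor * L
    } else if (a == "ANTAG_REVERSED") {
      tt$lfc_e2[i] <- s * L
      tt$lfc_r5020[i] <- -s * effect$reversed_r_factor * L
      tt$lfc_combo[i] <- -s * effect$reversed_combo_factor * L
    }
  }
  attr(tt, "effect") <- effect
  tt
}

#' Expected log2 shift of every gene in one factorial cell
#'
#' The generative model is additive on the log2 scale: ligand-independent
#' shift (PR lines only) + treatment effects, with the FFF/QQQ multipliers
#' acting on the progestin component and the unliganded-PR modulation factor
#' acting on the estrogen component in PR lines. EV carries only the
#' estrogen component.
#'
#' @param truth truth table from [generate_truth()].
#' @param cell_line one of EV, WT, FFF, QQQ.
#' @param treatment one of VEH, R5020, E2, E2R.
#' @return numeric vector of log2 shifts, one per gene.
#' @export
expected_shift <- function(truth, cell_line, treatment) {
  cell_line <- match.arg(cell_line, CELL_LINES)
  treatment <- match.arg(treatment, TREATMENTS)
  pr <- cell_line %in% PR_LINES
  rmult <- switch(cell_line,
    EV = 0, WT = rep(1, nrow(truth)), FFF = truth$atten_fff, QQQ = truth$hyper_qqq)
  e2mult <- if (pr) truth$e2_mod else rep(1, nrow(truth))
  base <- if (pr) truth$lfc_li else rep(0, nrow(truth))
  tr <- switch(treatment,
    VEH = 0,
    R5020 = if (pr) truth$lfc_r5020 * rmult else 0,
    E2 = truth$lfc_e2 * e2mult,
    E2R = if (pr) {
      truth$lfc_combo + (rmult - 1) * truth$lfc_r5020 + (e2mult - 1) * truth$lfc_e2
    } else {
      truth$lfc_e2
    })
  base + tr
}

#' Write / read a truth table as TSV
#'
#' Column dictionary: `gene_id` (string), `archetype` (one of [ARCHETYPES]),
#' `base_mean` (expected count in EV vehicle), `dispersion` (NB
#' overdispersion), `lfc_r5020`/`lfc_e2`/`lfc_combo` (log2 treatment effects
#' in the wild-type PR line), `lfc_li` (constitutive unliganded shift),
#' `atten_fff`/`hyper_qqq` (mutant multipliers on the progestin component),
#' `e2_mod` (unliganded multiplier on the estrogen component in PR lines).
#'
#' @param truth truth table.
#' @param path file path.
#' @return `read_truth` returns the data.frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
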