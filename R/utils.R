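# Internal helpers: seeded substreams and input validation.

CELL_LINES <- c("EV", "WT", "FFF", "QQQ")
TREATMENTS <- c("VEH", "R5020", "E2", "E2R")
PR_LINES <- c("WT", "FFF", "QQQ")

#' Derive a reproducible substream seed
#'
#' Maps a (seed, index, salt) triple to a deterministic 32-bit seed so that
#' every gene, sample or peak owns its own RNG substream. Adding entities to
#' a simulation therefore never perturbs the draws of earlier entities.
#'
#' @param seed master integer seed.
#' @param index entity counter (1-based).
#' @param salt stream family discriminator (one value per draw type).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, index, salt = 0) {
  m <- 2147483647 # 2^31 - 1, prime
  v <- as.numeric(seed) %% m
  v <- (v * 48271 + as.numeric(index) * 16807 + as.numeric(salt) * 69621) %% m
  as.integer(v)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Validate a factorial design sheet
#'
#' Checks the invariants of the sample sheet: unique sample ids, known
#' factor levels, and the study's replication floor (2 for RNA, 3 for ChIP).
#'
#' @param design data.frame with columns `sample_id`, `cell_line`,
#'   `treatment`, `replicate`, `assay`.
#' @param require_replicates enforce the per-assay replicate minimum.
#' @return the design, invisibly.
#' @export
validate_design <- function(design, require_replicates = TRUE) {
  need <- c("sample_id", "cell_line", "treatment", "replicate", "assay")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop("design sample_ids must be unique")
  if (!all(design$cell_line %in% CELL_LINES)) {
    stop("unknown cell_line; expected one of ", paste(CELL_LINES, collapse = ", "))
  }
  if (!all(design$treatment %in% TREATMENTS)) {
    stop("unknown treatment; expected one of ", paste(TREATMENTS, collapse = ", "))
  }
  if (!all(design$assay %in% c("RNA", "CHIP"))) stop("assay must be RNA or CHIP")
  if (require_replicates) {
    tab <- table(paste(design$cell_line, design$treatment), design$assay)
    if ("RNA" %in% colnames(tab) && any(tab[, "RNA"] > 0 & tab[, "RNA"] < 2)) {
      stop("RNA design requires >= 2 replicates per (cell_line, treatment)")
    }
    if ("CHIP" %in% colnames(tab) && any(tab[, "CHIP"] > 0 & tab[, "CHIP"] < 3)) {
      stop("ChIP design requires >= 3 replicates per condition")
    }
  }
  invisible(design)
}

condition_key <- function(design) paste(design$cell_line, design$treatment, sep = ":")
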