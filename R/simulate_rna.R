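# Factorial RNA-Seq count simulation with known ground truth.

#' Build the factorial RNA-Seq sample sheet
#'
#' Default mirrors the study design: 4 cell lines x 4 treatments with
#' biological duplicates.
#'
#' @param cell_lines,treatments factor levels to include.
#' @param n_rep replicates per condition (>= 2).
#' @return design data.frame (`sample_id`, `cell_line`, `treatment`,
#'   `replicate`, `assay`).
#' @export
make_rna_design <- function(cell_lines = CELL_LINES, treatments = TREATMENTS,
                            n_rep = 2) {
  d <- expand.grid(replicate = seq_len(n_rep), treatment = treatments,
                   cell_line = cell_lines, stringsAsFactors = FALSE)
  d <- d[, c("cell_line", "treatment", "replicate")]
  d$sample_id <- sprintf("%s_%s_r%d", d$cell_line, d$treatment, d$replicate)
  d$assay <- "RNA"
  validate_design(d)
  d[, c("sample_id", "cell_line", "treatment", "replicate", "assay")]
}

#' Simulate a factorial RNA-Seq count matrix
#'
#' Counts are negative binomial with mean
#' `base_mean * 2^shift(gene, cell line, treatment) * size factor` and the
#' gene's dispersion; dispersion 0 degenerates to Poisson. Library size
#' factors are log-normal with configurable spread. Each gene and each
#' sample's size factor use dedicated RNG substreams, so the matrix is
#' reproducible gene-by-gene.
#'
#' @param truth truth table from [generate_truth()].
#' @param design RNA design sheet from [make_rna_design()].
#' @param library_size_spread standard deviation of log size factors.
#' @param seed integer master seed.
#' @param size_factors optional fixed per-sample size factors (overrides the
#'   log-normal draw; useful for controlled experiments).
#' @return list with `counts` (genes x samples integer matrix), `design`,
#'   and `size_factors` (the true simulated ones).
#' @export
simulate_expression_counts <- function(truth, design, library_size_spread = 0.2,
                                       seed = 1, size_factors = NULL) {
  validate_design(design, require_replicates = FALSE)
  if (!all(design$assay == "RNA")) stop("design assay must be RNA")
  if (any(truth$base_mean <= 0)) stop("base_mean must be positive")
  if (any(truth$dispersion < 0)) stop("dispersion must be >= 0")
  stopifnot_scalar_number(library_size_spread, "library_size_spread", positive = TRUE)

  n_g <- nrow(truth)
  n_s <- nrow(design)
  if (is.null(size_factors)) {
    size_factors <- vapply(seq_len(n_s), function(j) {
      withr::with_seed(substream_seed(seed, j, salt = 101),
                       exp(stats::rnorm(1, 0, library_size_spread)))
    }, numeric(1))
  } else if (length(size_factors) != n_s || any(size_factors <= 0)) {
    stop("size_factors must be positive, one per sample")
  }
  names(size_factors) <- design$sample_id

  # expected shift per condition, looked up per sample column
  conds <- unique(design[, c("cell_line", "treatment")])
  shift_by_cond <- matrix(0, n_g, nrow(conds))
  for (k in seq_len(nrow(conds))) {
    shift_by_cond[, k] <- expected_shift(truth, conds$cell_line[k], conds$treatment[k])
  }
  cond_of_sample <- match(condition_key(design),
                          paste(conds$cell_line, conds$treatment, sep = ":"))

  counts <- matrix(0L, n_g, n_s, dimnames = list(truth$gene_id, design$sample_id))
  for (g in seq_len(n_g)) {
    mu <- truth$base_mean[g] * 2^shift_by_cond[g, cond_of_sample] * size_factors
    disp <- truth$dispersion[g]
    counts[g, ] <- withr::with_seed(substream_seed(seed, g, salt = 102), {
      if (disp == 0) stats::rpois(n_s, mu) else stats::rnbinom(n_s, mu = mu, size = 1 / disp)
    })
  }
  list(counts = counts, design = design, size_factors = size_factors)
}

#' Write / read a count matrix with its sample sheet
#'
#' Counts TSV: first column `gene_id`, remaining columns the sample ids in
#' sample-sheet order. Design TSV columns: `sample_id`, `cell_line`,
#' `treatment`, `replicate`, `assay`.
#'
#' @param counts genes x samples matrix.
#' @param design sample sheet.
#' @param counts_path,design_path output paths.
#' @return `read_counts` returns `list(counts, design)`.
#' @export
write_counts <- function(counts, design, counts_path, design_path) {
  stopifnot(identical(colnames(counts), design$sample_id))
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(design, design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, design_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$gene_id
  if (!identical(colnames(counts), design$sample_id)) {
    stop("count columns do not match the sample sheet")
  }
  list(counts = counts, design = design)
}
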