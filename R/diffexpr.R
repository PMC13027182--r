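# Self-contained negative-binomial differential-expression engine:
# median-of-ratios normalization, method-of-moments dispersion with trend
# shrinkage, per-condition NB mean MLE, Wald contrasts, BH adjustment.
#
# This is a deliberately fully-specified engine: gene-wise MoM dispersion
# shrunk 50% toward a fitted mean-dispersion trend (no empirical-Bayes MAP),
# no independent filtering, no LFC shrinkage. Downstream classifiers consume
# only (log2FoldChange, pvalue, padj).

#' Median-of-ratios size factors
#'
#' For sample j, the factor is the median over genes (with positive counts in
#' every sample) of `counts[g, j] / geometric mean of gene g`, rescaled to
#' unit geometric mean across samples.
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
compute_size_factors <- function(counts) {
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative and complete")
  loggeo <- rowMeans(log(counts))
  if (!any(is.finite(loggeo))) {
    stop("no gene has nonzero counts in every sample; filter all-zero-containing ",
         "genes or provide deeper data before normalization")
  }
  sf <- apply(counts, 2, function(x) {
    exp(stats::median((log(x) - loggeo)[is.finite(loggeo) & x > 0]))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("size factors must be finite and > 0")
  # unit geometric mean: fixes the arbitrary global scale, so rescaling one
  # sample's counts by c changes exactly that sample's factor (by c) and
  # leaves every normalized quantity untouched
  sf / exp(mean(log(sf)))
}

#' Gene-wise dispersion by method of moments with trend shrinkage
#'
#' Raw estimate per gene: df-weighted average over replicated conditions of
#' `(s^2 - m) / m^2` on normalized counts, truncated at 0 (the Poisson
#' limit). A mean-dispersion trend `a0 + a1/mu` is fitted to the positive raw
#' estimates and the final value is
#' `(1 - trend_weight) * raw + trend_weight * trend(mu)`.
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors from [compute_size_factors()].
#' @param design sample sheet; conditions are (cell_line, treatment) groups.
#' @param trend_weight shrinkage weight toward the trend (default 0.5).
#' @return data.frame `gene_id`, `mu` (mean normalized count), `disp_raw`,
#'   `disp_trend`, `disp`, `status` (`ok`, `trend_only` for genes with no
#'   replicated information, `untestable` for all-zero genes).
#' @export
estimate_dispersions <- function(counts, sf, design, trend_weight = 0.5) {
  if (trend_weight < 0 || trend_weight > 1) stop("trend_weight must lie in [0, 1]")
  norm <- sweep(counts, 2, sf, "/")
  groups <- condition_key(design)
  mu <- rowMeans(norm)

  num <- rep(0, nrow(counts))
  dfs <- rep(0, nrow(counts))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    n <- length(idx)
    if (n < 2) next
    x <- norm[, idx, drop = FALSE]
    m <- rowMeans(x)
    v <- (rowSums(x^2) - n * m^2) / (n - 1)
    est <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    w <- ifelse(is.na(est), 0, n - 1)
    num <- num + ifelse(is.na(est), 0, est * (n - 1))
    dfs <- dfs + w
  }
  signed_raw <- ifelse(dfs > 0, num / dfs, NA_real_)
  disp_raw <- pmax(0, signed_raw)

  # mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted to the signed MoM
  # values (truncating at 0 first would bias the trend upward at low
  # dispersion). The fit is iteratively variance-weighted: sd(raw) scales
  # like (alpha + 1/mu), so unweighted OLS would let the noisy low-mu genes
  # set the intercept that high-mu genes then inherit.
  fit_ok <- !is.na(signed_raw) & mu > 0
  if (sum(fit_ok) >= 10) {
    x <- 1 / mu[fit_ok]
    y <- signed_raw[fit_ok]
    a0 <- max(mean(y), 0); a1 <- 0
    for (it in 1:3) {
      sdscale <- pmax(pmax(a0 + a1 * x, 0) + x, 1e-8)
      keep <- abs(y - (a0 + a1 * x)) <= 10 * sdscale
      co <- stats::coef(stats::lm(y ~ x, weights = 1 / sdscale^2, subset = keep))
      a0 <- max(0, co[[1]]); a1 <- max(0, co[[2]])
    }
  } else {
    # too little replicated information to learn a trend: fall back to a
    # weakly-informative prior scale typical of bulk RNA-Seq
    a0 <- 0.1; a1 <- 1
  }
  disp_trend <- ifelse(mu > 0, a0 + a1 / mu, a0)

  # shrink toward the trend; the trend also acts as a floor so that the
  # heavy downward sampling noise of few-replicate MoM estimates cannot
  # produce anti-conservative standard errors
  disp <- (1 - trend_weight) * ifelse(is.na(disp_raw), disp_trend, disp_raw) +
    trend_weight * disp_trend
  disp <- pmax(disp, disp_trend, 0)

  status <- rep("ok", nrow(counts))
  status[is.na(disp_raw)] <- "trend_only"
  allzero <- rowSums(counts) == 0
  disp[allzero] <- 0
  status[allzero] <- "untestable"
  data.frame(gene_id = rownames(counts), mu = mu, disp_raw = disp_raw,
             disp_trend = disp_trend, disp = disp, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Specify a two-condition contrast
#'
#' Either a treatment contrast within one cell line (`cell_line` fixed,
#' `numerator`/`denominator` are treatments) or a cell-line contrast at a
#' fixed treatment (`treatment` fixed, `numerator`/`denominator` are cell
#' lines).
#'
#' @param numerator,denominator the compared levels (numerator on top of the
#'   fold change).
#' @param cell_line fix a cell line (treatment contrast) ...
#' @param treatment ... or fix a treatment (cell-line contrast).
#' @return an object of class `praf1_contrast`.
#' @export
contrast_spec <- function(numerator, denominator, cell_line = NULL, treatment = NULL) {
  if (identical(numerator, denominator)) stop("numerator must differ from denominator")
  if (is.null(cell_line) == is.null(treatment)) {
    stop("specify exactly one of cell_line (treatment contrast) or treatment ",
         "(cell-line contrast)")
  }
  structure(list(numerator = numerator, denominator = denominator,
                 cell_line = cell_line, treatment = treatment),
            class = "praf1_contrast")
}

contrast_samples <- function(design, contrast) {
  pick <- function(level) {
    if (!is.null(contrast$cell_line)) {
      design$cell_line == contrast$cell_line & design$treatment == level
    } else {
      design$treatment == contrast$treatment & design$cell_line == level
    }
  }
  num <- which(pick(contrast$numerator))
  den <- which(pick(contrast$denominator))
  if (!length(num) || !length(den)) stop("contrast conditions absent from design")
  if (length(num) < 2 || length(den) < 2) {
    warning("contrast has a condition with a single replicate; ",
            "inference relies entirely on the supplied dispersions")
  }
  list(num = num, den = den)
}

# Per-condition NB mean MLE on the normalized scale, vectorized over genes.
# Solves d/dq sum_i [k_i log(s_i q) - (k_i + 1/a) log(s_i q + 1/a)] = 0 by
# damped Newton iteration; the Poisson case has the closed form sum k / sum s.
nb_condition_fit <- function(K, s, alpha) {
  tot <- rowSums(K)
  q <- tot / sum(s)
  pois <- alpha == 0
  act <- which(!pois & q > 0)
  if (length(act)) {
    qa <- q[act]
    Ka <- K[act, , drop = FALSE]
    r <- 1 / alpha[act]
    for (it in 1:100) {
      sq <- outer(qa, s) # mu matrix
      denom <- sweep(sq, 1, r, "+")
      f <- tot[act] / qa - rowSums(sweep((Ka + r) / denom, 2, s, "*"))
      fp <- -tot[act] / qa^2 + rowSums(sweep((Ka + r) / denom^2, 2, s^2, "*"))
      step <- f / fp
      step[!is.finite(step)] <- 0
      qn <- qa - step
      qn <- pmin(pmax(qn, qa / 4), qa * 4) # damping
      conv <- abs(qn - qa) < 1e-10 * (qa + 1e-8)
      qa <- qn
      if (all(conv)) break
    }
    q[act] <- qa
  }
  q
}

#' Negative-binomial Wald contrast
#'
#' Fits the NB mean of each gene per condition on the normalized scale,
#' reports `log2FoldChange = log2(q_num / q_den)` with condition means
#' floored at `mean_floor` normalized counts, a delta-method standard error
#' from the expected Fisher information, the Wald statistic and its
#' two-sided normal p-value, and BH-adjusted p-values over the testable
#' genes.
#'
#' Status codes: `ok`; `floored` when both condition means sit at the floor
#' (log2FoldChange forced to 0, p to 1); `untestable` when all counts are
#' zero on both sides (excluded from the BH denominator, `pvalue = NA`).
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors.
#' @param disp dispersion table from [estimate_dispersions()] or a numeric
#'   vector of per-gene dispersions.
#' @param design sample sheet.
#' @param contrast a [contrast_spec()].
#' @param mean_floor pseudo-mean floor on normalized condition means.
#' @return data.frame `gene_id`, `baseMean`, `log2FoldChange`, `lfcSE`,
#'   `stat`, `pvalue`, `padj`, `status`, with the contrast attached as
#'   attribute `"contrast"`.
#' @export
wald_test <- function(counts, sf, disp, design, contrast, mean_floor = 0.5) {
  idx <- contrast_samples(design, contrast)
  alpha <- if (is.data.frame(disp)) {
    stopifnot(identical(disp$gene_id, rownames(counts)))
    disp$disp
  } else {
    stopifnot(length(disp) == nrow(counts))
    as.numeric(disp)
  }
  if (any(alpha < 0) || anyNA(alpha)) stop("dispersions must be nonnegative")

  fit_side <- function(cols) {
    K <- counts[, cols, drop = FALSE]
    s <- sf[cols]
    q <- nb_condition_fit(K, s, alpha)
    qf <- pmax(q, mean_floor)
    # expected information for log q: I = q * sum_i s_i / (1 + alpha s_i q)
    denom <- 1 + alpha * outer(qf, s) # alpha recycles down columns (per gene)
    info <- qf * rowSums(sweep(1 / denom, 2, s, "*"))
    list(q = q, qf = qf, var_log2 = 1 / (info * log(2)^2),
         zero = rowSums(K) == 0)
  }
  num <- fit_side(idx$num)
  den <- fit_side(idx$den)

  lfc <- log2(num$qf / den$qf)
  se <- sqrt(num$var_log2 + den$var_log2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))

  status <- rep("ok", nrow(counts))
  floored <- num$q < mean_floor & den$q < mean_floor
  untest <- num$zero & den$zero
  lfc[floored] <- 0
  stat[floored] <- 0
  p[floored] <- 1
  status[floored] <- "floored"
  p[untest] <- NA_real_
  status[untest] <- "untestable"

  norm <- sweep(counts[, c(idx$num, idx$den), drop = FALSE], 2,
                sf[c(idx$num, idx$den)], "/")
  res <- data.frame(
    gene_id = rownames(counts),
    baseMean = rowMeans(norm),
    log2FoldChange = lfc, lfcSE = se, stat = stat, pvalue = p,
    padj = adjust_bh(p), status = status,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "contrast") <- contrast
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over the testable p-values; `NA` entries
#' (untestable genes) are excluded from the multiple-testing denominator and
#' returned as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed, NaN is an
#'   error).
#' @return vector of adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(is.nan(p))) stop("NaN p-values are not allowed")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Write a DE result table as TSV
#'
#' Fixed column order (`gene_id`, `baseMean`, `log2FoldChange`, `lfcSE`,
#' `stat`, `pvalue`, `padj`) for comparison with conventional DE output.
#' @param de DE result from [wald_test()].
#' @param path output path.
#' @export
write_de_result <- function(de, path) {
  cols <- c("gene_id", "baseMean", "log2FoldChange", "lfcSE", "stat", "pvalue", "padj")
  utils::write.table(de[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
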