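#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across contigs (restricted
#' to contigs with a positive geometric mean over samples) of the ratio of
#' that sample's count to the contig's geometric mean. This is the classic
#' count-normalisation used for bulk RNA-seq.
#'
#' @param x a [count_matrix()] or a plain numeric matrix.
#' @return A positive numeric vector of per-sample scale factors, named by
#'   sample.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  if (all(m == 0)) stop("all-zero count matrix: size factors undefined")
  log_geo <- rowMeans(log(m))           # -Inf for rows containing a zero
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no contig has all-positive counts; size factors undefined")
  sf <- apply(m[use, , drop = FALSE], 2,
              function(col) exp(stats::median(log(col) - log_geo[use])))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factors; check for samples with only zeros")
  sf
}

#' FPKM from a count matrix
#'
#' `fpkm = count / ((length / 1e3) * (library_size / 1e6))`, with library
#' size the raw column sum. Fractional counts enter as-is.
#'
#' @param x a [count_matrix()].
#' @return A numeric matrix of FPKM values, same shape as the counts.
#' @export
fpkm <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- colSums(x$counts)
  if (any(lib == 0)) stop("zero library size in sample: ",
                          paste(colnames(x$counts)[lib == 0], collapse = ", "))
  sweep(x$counts / (x$lengths / 1e3), 2, lib / 1e6, "/")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; order-preserving with monotonicity
#' enforcement, output clipped to `[0, 1]`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-contig negative-binomial Wald test, mutant vs control
#'
#' Counts are normalised by median-of-ratios size factors (computed on the
#' samples entering the comparison) and rounded to the nearest integer. Per
#' contig, the log2 fold change is taken between pseudocounted group means of
#' normalised counts; dispersion is estimated per contig by method of moments
#' (pooled within-group variance, floored at zero); the Wald statistic is the
#' fold change over its delta-method standard error under NB variance
#' `mu + dispersion * mu^2`. Two-sided p-values use a t reference with
#' `n1 + n2 - 2` degrees of freedom, which accounts for the noise of the
#' plug-in dispersion at the few-replicate sizes typical of pooled-embryo
#' designs; with one sample per group the dispersion is unidentifiable and a
#' Poisson-variance normal reference is used with a warning.
#'
#' With `stratify_by_batch = TRUE`, the test runs per batch and combines
#' per-batch log2 fold changes by inverse-variance weighting; degrees of
#' freedom add across batches.
#'
#' @param x a [count_matrix()].
#' @param sheet sample sheet; `condition` must contain both "mutant" and
#'   "control" among the selected samples.
#' @param stratify_by_batch estimate per batch and pool (default `FALSE`).
#' @param pseudocount added to group means before taking logs (default 0.5).
#' @return A data.frame: `contig_id`, `base_mean`, `log2fc`, `se`, `df`,
#'   `p_value`.
#' @export
nb_test <- function(x, sheet, stratify_by_batch = FALSE, pseudocount = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  sheet <- validate_sample_sheet(sheet)
  miss <- setdiff(sheet$sample_id, colnames(x$counts))
  if (length(miss))
    stop("sample(s) absent from count matrix: ", paste(miss, collapse = ", "))
  counts <- x$counts[, sheet$sample_id, drop = FALSE]
  for (grp in c("mutant", "control"))
    if (!any(sheet$condition == grp))
      stop("comparison needs at least one '", grp, "' sample")
  sf <- size_factors(counts)
  norm <- sweep(round(counts), 2, sf, "/")
  batches <- if (stratify_by_batch) unique(sheet$batch) else "all"
  per_batch <- lapply(batches, function(b) {
    keep <- if (identical(b, "all")) rep(TRUE, nrow(sheet))
            else sheet$batch == b
    nb_wald_stratum(norm[, keep, drop = FALSE],
                    sheet$condition[keep], pseudocount)
  })
  if (length(per_batch) == 1L) {
    res <- per_batch[[1L]]
  } else {
    w <- sapply(per_batch, function(b) 1 / b$var_lfc)  # contigs x batches
    w[!is.finite(w)] <- 0
    wsum <- rowSums(w)
    lfc_mat <- sapply(per_batch, `[[`, "log2fc")
    lfc <- ifelse(wsum > 0, rowSums(w * lfc_mat) / wsum, 0)
    var_lfc <- ifelse(wsum > 0, 1 / wsum, Inf)
    df <- rowSums(sapply(per_batch, `[[`, "df"))
    res <- list(log2fc = lfc, var_lfc = var_lfc, df = df)
  }
  se <- sqrt(res$var_lfc)
  tstat <- ifelse(se > 0 & is.finite(se), res$log2fc / se, 0)
  p <- ifelse(res$df >= 1,
              2 * stats::pt(-abs(tstat), df = pmax(res$df, 1)),
              2 * stats::pnorm(-abs(tstat)))
  p[!is.finite(se) | se == 0] <- 1
  data.frame(contig_id = rownames(counts),
             base_mean = rowMeans(norm),
             log2fc = res$log2fc, se = se, df = res$df,
             p_value = pmin(p, 1), stringsAsFactors = FALSE,
             row.names = NULL)
}

# Wald components for one stratum of samples. Returns per-contig log2fc,
# delta-method variance of log2fc, and residual degrees of freedom.
nb_wald_stratum <- function(norm, condition, pseudocount) {
  i1 <- condition == "control"
  i2 <- condition == "mutant"
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  df <- n1 + n2 - 2L
  if (df >= 1) {
    ss <- rowSums((norm[, i1, drop = FALSE] - m1)^2) +
      rowSums((norm[, i2, drop = FALSE] - m2)^2)
    s2 <- ss / df
    mbar <- rowMeans(norm)
    disp <- ifelse(mbar > 0, pmax(0, (s2 - mbar) / mbar^2), 0)
  } else {
    warning("one sample per group: dispersion unidentifiable, ",
            "assuming Poisson variance", call. = FALSE)
    disp <- 0
  }
  v1 <- (m1 + disp * m1^2) / n1
  v2 <- (m2 + disp * m2^2) / n2
  var_lfc <- (v1 / (m1 + pseudocount)^2 + v2 / (m2 + pseudocount)^2) /
    log(2)^2
  var_lfc[m1 + m2 == 0] <- Inf
  list(log2fc = log2(m2 + pseudocount) - log2(m1 + pseudocount),
       var_lfc = var_lfc, df = rep(df, length(m1)))
}

# The differential-expression predicate, shared by apply_deg_filter() and
# dge_analysis(). Strict inequalities exactly as in the filter definition.
deg_pass <- function(log2fc, p_adjusted, fpkm_best,
                     lfc_min = 0.5, alpha = 0.05, fpkm_min = 2) {
  abs(log2fc) > lfc_min & p_adjusted < alpha & fpkm_best > fpkm_min
}

#' Apply the differential-expression filter
#'
#' A contig passes iff `|log2fc| > lfc_min` AND `p_adjusted < alpha` AND its
#' best condition FPKM `> fpkm_min` — all strict inequalities. Defaults are
#' the pipeline's filter: 0.5 log2, adjusted p 0.05, 2 FPKM in at least one
#' condition.
#'
#' @param results a data.frame with columns `contig_id`, `log2fc`,
#'   `p_adjusted`, and `fpkm_mutant`/`fpkm_control` (or a precomputed
#'   `fpkm_best`).
#' @param lfc_min,alpha,fpkm_min filter thresholds.
#' @return Character vector of passing contig ids.
#' @export
apply_deg_filter <- function(results, lfc_min = 0.5, alpha = 0.05,
                             fpkm_min = 2) {
  fb <- if ("fpkm_best" %in% names(results)) results$fpkm_best
        else pmax(results$fpkm_mutant, results$fpkm_control)
  results$contig_id[deg_pass(results$log2fc, results$p_adjusted, fb,
                             lfc_min, alpha, fpkm_min)]
}

#' Full differential-expression analysis
#'
#' Chains [nb_test()], [bh_adjust()], per-condition FPKM summaries and the
#' filter into one results table.
#'
#' @inheritParams nb_test
#' @param lfc_min,alpha,fpkm_min filter thresholds (see [apply_deg_filter()]).
#' @param fpkm_mode `"condition_mean"` (condition FPKM = mean over that
#'   condition's samples; default) or `"max_sample"` (maximum single sample
#'   within the condition).
#' @return A data.frame with `contig_id`, `base_mean`, `log2fc`, `se`, `df`,
#'   `p_value`, `p_adjusted`, `fpkm_mutant`, `fpkm_control`, `passes_filter`.
#' @export
dge_analysis <- function(x, sheet, stratify_by_batch = FALSE,
                         lfc_min = 0.5, alpha = 0.05, fpkm_min = 2,
                         fpkm_mode = c("condition_mean", "max_sample")) {
  fpkm_mode <- match.arg(fpkm_mode)
  sheet <- validate_sample_sheet(sheet)
  res <- nb_test(x, sheet, stratify_by_batch = stratify_by_batch)
  res$p_adjusted <- bh_adjust(res$p_value)
  fk <- fpkm(x[, sheet$sample_id])
  summarise <- function(cond) {
    cols <- sheet$sample_id[sheet$condition == cond]
    block <- fk[, cols, drop = FALSE]
    if (fpkm_mode == "condition_mean") rowMeans(block)
    else apply(block, 1, max)
  }
  res$fpkm_mutant <- summarise("mutant")
  res$fpkm_control <- summarise("control")
  res$passes_filter <- deg_pass(res$log2fc, res$p_adjusted,
                                pmax(res$fpkm_mutant, res$fpkm_control),
                                lfc_min, alpha, fpkm_min)
  res
}

#' PCA-based sample quality control
#'
#' Principal components of `log2(normalised count + 1)` over the most
#' variable contigs. A sample is flagged as an outlier when its distance to
#' its condition centroid in the PC1/PC2 plane exceeds three times the median
#' within-condition distance.
#'
#' @param x a [count_matrix()].
#' @param sheet sample sheet covering the samples of `x`.
#' @param n_top number of most-variable contigs used (default 500).
#' @return A list of class `qc_report`: `coords` (data.frame with
#'   `sample_id`, `PC1`, `PC2`, `condition`, `batch`, `centroid_dist`),
#'   `flagged` (character), `var_explained` (first two proportions).
#' @export
pca_qc <- function(x, sheet, n_top = 500) {
  stopifnot(inherits(x, "count_matrix"))
  sheet <- validate_sample_sheet(sheet)
  counts <- x$counts[, sheet$sample_id, drop = FALSE]
  if (ncol(counts) < 3) stop("PCA QC needs at least 3 samples")
  sf <- size_factors(counts)
  lg <- log2(sweep(counts, 2, sf, "/") + 1)
  v <- apply(lg, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(lg)))]
  pc <- stats::prcomp(t(lg[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- matrix(0, ncol(counts), 2,
                   dimnames = list(colnames(counts), c("PC1", "PC2")))
  coords[, seq_len(k)] <- pc$x[, seq_len(k)]
  conds <- unique(sheet$condition)
  cent <- t(vapply(conds, function(cc)
    colMeans(coords[sheet$condition == cc, , drop = FALSE]), numeric(2)))
  d <- sqrt(rowSums((coords - cent[sheet$condition, , drop = FALSE])^2))
  med <- stats::median(d)
  flagged <- sheet$sample_id[d > 3 * med]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    coords = data.frame(sample_id = sheet$sample_id,
                        PC1 = coords[, 1], PC2 = coords[, 2],
                        condition = sheet$condition, batch = sheet$batch,
                        centroid_dist = d, stringsAsFactors = FALSE,
                        row.names = NULL),
    flagged = flagged,
    var_explained = ve[seq_len(min(2, length(ve)))]),
    class = "qc_report")
}
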