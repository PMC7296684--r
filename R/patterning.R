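#' Read a tissue expression matrix from TSV
#'
#' First column gene id, remaining columns one per tissue (header row gives
#' tissue labels); values are mean expression per gene per tissue. Units are
#' irrelevant to the enrichment rule, which only compares values within a
#' gene.
#'
#' @param path path to a tab-separated file.
#' @return A numeric matrix, genes in rows, tissues in columns.
#' @export
read_tissue_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene id in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression value in ", path)
  if (any(m < 0)) stop("negative expression value in ", path)
  rownames(m) <- ids
  m
}

#' Write a tissue expression matrix to TSV
#'
#' @param m numeric gene-by-tissue matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tissue_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify gut-enriched genes from adult-tissue expression
#'
#' A gene is gut-enriched iff, after dropping excluded tissues (eggs and
#' embryos by default):
#' \enumerate{
#'   \item its mean expression in the target tissue is strictly higher than
#'     in every other retained tissue, and
#'   \item the target level is at least `fold` times the level of at least
#'     `rule_k` of the `m` other tissues (non-strict; a zero other-tissue
#'     value counts as satisfied when the target value is positive).
#' }
#' The rule is scale-free: it is invariant to multiplying the whole matrix by
#' a positive constant and to permuting the non-target tissue columns.
#'
#' @param m numeric gene-by-tissue matrix (see [read_tissue_matrix()]).
#' @param target target tissue label (default `"gut"`).
#' @param excluded tissue labels ignored by the rule (default eggs, embryos;
#'   labels absent from the matrix are tolerated).
#' @param fold fold threshold of clause 2 (default 2).
#' @param rule_k minimum number of other tissues clause 2 must hold in
#'   (default 7, of the study's 8 other adult tissues).
#' @return A list: `genes` (character vector of enriched gene ids) and
#'   `diagnostics` (data.frame per gene: `gene`, `target_value`,
#'   `max_other`, `strictly_highest`, `n_fold_satisfied`, `enriched`).
#' @export
classify_gut_enriched <- function(m, target = "gut",
                                  excluded = c("eggs", "embryos"),
                                  fold = 2, rule_k = 7) {
  if (!target %in% colnames(m)) stop("target tissue '", target,
                                     "' absent from matrix")
  if (target %in% excluded) stop("target tissue cannot be excluded")
  others <- setdiff(colnames(m), c(target, excluded))
  n_other <- length(others)
  if (n_other < 1) stop("no non-target tissues remain after exclusion")
  if (rule_k > n_other)
    stop("rule_k (", rule_k, ") exceeds the ", n_other, " other tissues")
  tv <- m[, target]
  om <- m[, others, drop = FALSE]
  strictly_highest <- tv > apply(om, 1, max)
  fold_ok <- (tv >= fold * om) | (om == 0 & tv > 0)
  n_fold <- rowSums(fold_ok)
  enriched <- strictly_highest & n_fold >= rule_k
  diag <- data.frame(gene = rownames(m), target_value = tv,
                     max_other = apply(om, 1, max),
                     strictly_highest = strictly_highest,
                     n_fold_satisfied = n_fold, enriched = enriched,
                     stringsAsFactors = FALSE, row.names = NULL)
  list(genes = rownames(m)[enriched], diagnostics = diag)
}

#' Transfer a gene set to assembly contigs through a BLAST hit table
#'
#' Any-hit transfer: a contig is selected iff at least one gene of the set
#' hits it with an e-value at or below the cutoff. One gene may mark several
#' contigs and a contig needs only one qualifying hit; duplicates collapse to
#' a set.
#'
#' @param genes character vector of gene ids.
#' @param hits hit table (see [read_hit_table()]): queries are genes,
#'   subjects are contigs.
#' @param evalue_max e-value cutoff (default 1e-70).
#' @return Character vector of contig ids.
#' @export
map_genes_to_contigs <- function(genes, hits, evalue_max = 1e-70) {
  keep <- hits$query_gene %in% genes & hits$e_value <= evalue_max
  unique(hits$subject_contig[keep])
}

#' Overlap counts between gut-enriched contigs and two DEG sets
#'
#' @param gut_contigs,deg_a,deg_b character vectors of contig ids.
#' @return A list: `n_gut`, `n_deg_a`, `n_deg_b`, `gut_and_a`, `gut_and_b`,
#'   `gut_and_both`, `pct_of_a`, `pct_of_b` (the gut overlaps as percentages
#'   of each DEG set).
#' @export
venn_counts <- function(gut_contigs, deg_a, deg_b) {
  gut_contigs <- unique(gut_contigs)
  deg_a <- unique(deg_a); deg_b <- unique(deg_b)
  ga <- intersect(gut_contigs, deg_a)
  gb <- intersect(gut_contigs, deg_b)
  list(n_gut = length(gut_contigs),
       n_deg_a = length(deg_a), n_deg_b = length(deg_b),
       gut_and_a = length(ga), gut_and_b = length(gb),
       gut_and_both = length(intersect(ga, gb)),
       pct_of_a = if (length(deg_a)) 100 * length(ga) / length(deg_a) else 0,
       pct_of_b = if (length(deg_b)) 100 * length(gb) / length(deg_b) else 0)
}

#' Set-overlap enrichment: hypergeometric and permutation p-values
#'
#' Tests whether two contig sets overlap more than expected from random
#' draws out of a common universe. The upper-tail hypergeometric p-value is
#' `P(X >= x)` with `X ~ Hypergeom(|U|, |A|, |B|)`; the permutation p-value
#' redraws `|B|` elements from the universe `n_perm` times, with the +1
#' numerator/denominator correction.
#'
#' @param set_a,set_b character vectors (e.g. gut-enriched contigs and DEG
#'   contigs); must be subsets of `universe`.
#' @param universe character vector of all eligible contigs (typically the
#'   tested contigs).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation draw.
#' @return A list of class `enrichment_result`: `n_a`, `n_b`, `n_universe`,
#'   `overlap`, `pct_of_b`, `expected`, `p_hyper`, `p_perm`, `n_perm`,
#'   `seed`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe, n_perm = 10000,
                               seed = 1) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be subsets of the universe")
  n_u <- length(universe); n_a <- length(set_a); n_b <- length(set_b)
  x <- length(intersect(set_a, set_b))
  p_hyper <- if (n_a == 0 || n_b == 0) 1
             else stats::phyper(x - 1, n_a, n_u - n_a, n_b,
                                lower.tail = FALSE)
  if (!is.null(seed)) set.seed(seed)
  in_a <- universe %in% set_a
  exceed <- sum(vapply(seq_len(n_perm), function(i)
    sum(in_a[sample.int(n_u, n_b)]) >= x, logical(1)))
  structure(list(n_a = n_a, n_b = n_b, n_universe = n_u, overlap = x,
                 pct_of_b = if (n_b) 100 * x / n_b else 0,
                 expected = n_a * n_b / n_u,
                 p_hyper = p_hyper,
                 p_perm = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

#' Hox colinearity regression
#'
#' Ordinary least squares of per-gene log2 fold change on Hox paralog-group
#' index (1 = anterior-most). A negative slope means anterior groups respond
#' upward and posterior groups downward — the colinear-like signature. The
#' slope's significance is assessed both by the usual two-sided t-test and
#' by permutation of fold changes across indices.
#'
#' @param profile data.frame with columns `gene`, `group` (distinct positive
#'   integer paralog-group indices) and `log2fc`.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return A list of class `hox_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_t` (t-test on the slope), `p_perm` (two-sided permutation p on the
#'   slope), `n`, `n_perm`, `seed`.
#' @export
hox_colinearity <- function(profile, n_perm = 10000, seed = 1) {
  need <- c("gene", "group", "log2fc")
  if (!all(need %in% names(profile)))
    stop("profile needs columns: ", paste(need, collapse = ", "))
  if (nrow(profile) < 3) stop("regression needs at least 3 Hox genes")
  if (anyDuplicated(profile$group))
    stop("paralog-group indices must be distinct")
  if (length(unique(profile$group)) < 2 || stats::var(profile$group) == 0)
    stop("paralog-group indices are all identical")
  fit <- stats::lm(log2fc ~ group, data = profile)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  if (!is.null(seed)) set.seed(seed)
  perm_slopes <- vapply(seq_len(n_perm), function(i) {
    y <- sample(profile$log2fc)
    stats::cov(profile$group, y) / stats::var(profile$group)
  }, numeric(1))
  p_perm <- (sum(abs(perm_slopes) >= abs(slope)) + 1) / (n_perm + 1)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_t = sm$coefficients[2, 4],
                 p_perm = p_perm,
                 n = nrow(profile), n_perm = n_perm, seed = seed),
            class = "hox_fit")
}
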