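#' Mendelian-ratio chi-square test
#'
#' Two-category Pearson chi-square (focal genotype class versus the rest)
#' against expected proportions `(proportion, 1 - proportion)`, one degree of
#' freedom, no continuity correction. For a het x het cross the focal class
#' is homozygous mutants with expected proportion 1/4: e.g. 18 homozygotes
#' among 96 genotyped embryos gives chi-square 2.0, p = 0.157.
#'
#' @param observed count in the focal class.
#' @param total total genotyped.
#' @param proportion expected focal proportion, in (0, 1). Default 1/4.
#' @return A list: `chi2`, `p_value`, `df` (always 1), `expected` (focal
#'   expected count), `warning` (`NA` or a message when an expected cell is
#'   below 1).
#' @export
mendelian_chisq <- function(observed, total, proportion = 0.25) {
  stopifnot(total > 0, observed >= 0, observed <= total,
            proportion > 0, proportion < 1)
  expected <- c(total * proportion, total * (1 - proportion))
  warn <- if (any(expected < 1))
    "expected cell count below 1; chi-square approximation unreliable"
  else NA_character_
  ht <- suppressWarnings(
    stats::chisq.test(c(observed, total - observed),
                      p = c(proportion, 1 - proportion), correct = FALSE))
  list(chi2 = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter), expected = expected[1], warning = warn)
}

#' Count allele-discriminating reads in a FASTQ file
#'
#' A read is assigned to the wild-type (mutant) allele iff it contains the
#' wild-type (mutant) discriminating sequence as an exact substring on either
#' strand. Reads containing neither, or both, are excluded from the
#' classified totals and tallied separately.
#'
#' @param fastq path to a FASTQ file (gzip allowed).
#' @param junctions an [allele_junctions()] pair.
#' @param n_embryos embryos in the pool the library came from (recorded for
#'   downstream deconvolution).
#' @param beta assumed mutant-allele expression bias, recorded in the result.
#' @param pool_id identifier for the pool; defaults to the file name.
#' @return A `pool_allele_counts` object (see [pool_allele_counts()]).
#' @export
count_allele_reads <- function(fastq, junctions, n_embryos = 1, beta = 1,
                               pool_id = basename(fastq)) {
  stopifnot(inherits(junctions, "allele_junctions"))
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  hit_either_strand <- function(pattern) {
    fwd <- Biostrings::vcountPattern(pattern, reads) > 0
    rev <- Biostrings::vcountPattern(
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pattern))), reads) > 0
    fwd | rev
  }
  wt_hit <- hit_either_strand(junctions$wt)
  mut_hit <- hit_either_strand(junctions$mut)
  pool_allele_counts(pool_id = pool_id,
                     reads_wt = sum(wt_hit & !mut_hit),
                     reads_mut = sum(mut_hit & !wt_hit),
                     n_unclassified = sum(wt_hit == mut_hit),
                     n_embryos = n_embryos, beta = beta)
}

#' Wild-type read percentage of a pool
#'
#' `100 * reads_wt / (reads_wt + reads_mut)`, over classified reads only.
#'
#' @param p a `pool_allele_counts` object.
#' @return Percentage in `[0, 100]`.
#' @export
wt_read_fraction <- function(p) {
  stopifnot(inherits(p, "pool_allele_counts"))
  if (p$reads_total == 0) stop("no classified reads: fraction undefined")
  100 * p$reads_wt / p$reads_total
}

#' Expected wild-type read fraction for a pool of given composition
#'
#' Allele accounting: `n_wt` wild-type embryos contribute two wild-type
#' allele copies each and `n_het` heterozygotes one, the heterozygotes' other
#' copy being mutant and expressed at relative level `beta`. A 1:2 wt:het
#' control pool at `beta = 1` gives 2/3.
#'
#' @param n_wt,n_het wild-type and heterozygous embryo counts.
#' @param beta mutant-allele expression bias (> 0).
#' @return Expected fraction of wild-type reads among classified reads.
#' @export
expected_control_fraction <- function(n_wt, n_het, beta = 1) {
  stopifnot(n_wt + n_het >= 1, beta > 0)
  (2 * n_wt + n_het) / (2 * n_wt + n_het + beta * n_het)
}

# Expected wt read fraction of a mutant pool of n embryos of which k are
# heterozygous (the rest homozygous mutant): k wild-type allele copies out of
# 2n, mutant copies weighted by beta.
mutant_pool_fraction <- function(k, n, beta) {
  k / (k + beta * (2 * n - k))
}

#' Maximum-likelihood heterozygote count in a phenotype-sorted mutant pool
#'
#' Model: the pool holds `k` heterozygous and `n - k` homozygous-mutant
#' embryos, `k` in `0..n`; classified wild-type reads are
#' `Binomial(reads_total, f(k))` with
#' `f(k) = k / (k + beta * (2 n - k))`, clamped to `[eps, 1 - eps]` so the
#' boundary compositions stay finite under sequencing error. `f` is strictly
#' increasing in `k` for `beta > 0`, so the likelihood over `k` is unimodal.
#' An optional error rate folds into the expectation as
#' `f' = f (1 - e) + (1 - f) e`.
#'
#' @param p a `pool_allele_counts` object (`n_embryos`, `beta`, `error_rate`
#'   are taken from it unless overridden).
#' @param beta allele expression bias override.
#' @param error_rate read misclassification probability override.
#' @param eps likelihood clamp (default 1e-6).
#' @param support_drop log-likelihood drop defining the support interval
#'   (default 2).
#' @return A list: `k_hat` (MLE heterozygote count), `support` (integer
#'   vector `{k : logL(k) >= logL(k_hat) - support_drop}`), `log_lik`
#'   (profile over `k = 0..n`), `wt_percent` (observed wild-type read
#'   percentage).
#' @export
infer_pool_heterozygotes <- function(p, beta = p$beta,
                                     error_rate = p$error_rate, eps = 1e-6,
                                     support_drop = 2) {
  stopifnot(inherits(p, "pool_allele_counts"), p$n_embryos >= 1, beta > 0)
  if (p$reads_total == 0) stop("no classified reads: k not estimable")
  n <- p$n_embryos
  k <- 0:n
  f <- mutant_pool_fraction(k, n, beta)
  if (error_rate > 0) f <- f * (1 - error_rate) + (1 - f) * error_rate
  f <- pmin(pmax(f, eps), 1 - eps)
  ll <- stats::dbinom(p$reads_wt, p$reads_total, f, log = TRUE)
  k_hat <- k[which.max(ll)]
  list(k_hat = k_hat,
       support = k[ll >= max(ll) - support_drop],
       log_lik = stats::setNames(ll, k),
       wt_percent = wt_read_fraction(p))
}
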