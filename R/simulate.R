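#' Describe a heterozygote-by-heterozygote cross
#'
#' Offspring of a het x het cross segregate 1:2:1
#' (wild type : heterozygous : homozygous mutant). Only homozygotes show a
#' visible phenotype, so embryos are sorted into "mutant" and "control"
#' (sibling) pools by eye; `miscall_rate` is the probability that a
#' phenotypically normal (wt or het) embryo is nevertheless sorted into the
#' mutant pool.
#'
#' @param miscall_rate probability in `[0, 1)` of a non-homozygote landing in
#'   a mutant pool. Default 0.05, matching the contamination level implied by
#'   1-2 heterozygotes observed per mutant pool of 20 embryos.
#' @return A list of class `cross_design` with genotype probabilities
#'   `c(wt = 1/4, het = 1/2, hom = 1/4)` and the miscall rate.
#' @export
cross_design <- function(miscall_rate = 0.05) {
  if (!is.numeric(miscall_rate) || miscall_rate < 0 || miscall_rate >= 1)
    stop("miscall_rate must be in [0, 1)")
  structure(list(genotype_probs = c(wt = 0.25, het = 0.5, hom = 0.25),
                 miscall_rate = miscall_rate),
            class = "cross_design")
}

#' Simulate phenotype-sorted embryo pools from a het x het cross
#'
#' Mutant pools hold homozygotes plus `Binomial(pool_size, miscall_rate)`
#' contaminants; each contaminant is heterozygous with probability 2/3 and
#' wild type with probability 1/3 (the Mendelian ratio conditional on not
#' being homozygous). Control pools hold only wild-type and heterozygous
#' embryos in 1:2 expectation.
#'
#' @param design a [cross_design()].
#' @param n_pools number of pools to draw.
#' @param pool_size embryos per pool (the study pooled ~100 or ~300).
#' @param type `"mutant"` or `"control"`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A data.frame with columns `pool_id`, `type`, `n_embryos`, `n_wt`,
#'   `n_het`, `n_hom` (rows sum: `n_wt + n_het + n_hom == n_embryos`).
#' @export
simulate_cross_pools <- function(design, n_pools, pool_size,
                                 type = c("mutant", "control"), seed = NULL) {
  stopifnot(inherits(design, "cross_design"), pool_size >= 1, n_pools >= 1)
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  if (type == "mutant") {
    contam <- stats::rbinom(n_pools, pool_size, design$miscall_rate)
    n_het <- stats::rbinom(n_pools, contam, 2 / 3)
    n_wt <- contam - n_het
    n_hom <- pool_size - contam
  } else {
    n_het <- stats::rbinom(n_pools, pool_size, 2 / 3)
    n_wt <- pool_size - n_het
    n_hom <- rep(0L, n_pools)
  }
  data.frame(pool_id = sprintf("%s_pool_%02d", type, seq_len(n_pools)),
             type = type, n_embryos = pool_size,
             n_wt = n_wt, n_het = n_het, n_hom = n_hom,
             stringsAsFactors = FALSE)
}

#' Simulate a contig-by-sample count matrix with planted fold changes
#'
#' Counts are drawn from a negative binomial with variance
#' `mu + dispersion * mu^2`; `dispersion = 0` degenerates to Poisson. The
#' expected count of contig c in sample s is
#' `mean_profile[c] * size_factor[s] * 2^(lfc[c])` in mutant samples and
#' `mean_profile[c] * size_factor[s]` in control samples.
#'
#' @param truth a list with element `planted_lfc`: a numeric vector of true
#'   log2 fold changes named by contig id (zero for unaffected contigs), as
#'   built by [simulate_experiment()] or by hand.
#' @param sheet sample sheet (see [read_sample_sheet()]); its `condition`
#'   column decides which samples receive the fold change.
#' @param mean_profile positive numeric vector of baseline expected counts,
#'   one per contig (recycled if scalar).
#' @param dispersion per-contig NB dispersion (scalar recycled). Default 0.01:
#'   pools of hundreds of sibling embryos average out embryo-to-embryo
#'   biological variability, leaving near-technical replicate noise.
#' @param seed integer seed.
#' @param size_factors per-sample library scale factors; by default drawn
#'   log-uniformly from `[0.5, 2]`.
#' @param lengths contig lengths in nt; by default drawn uniformly from
#'   500-5000.
#' @return A [count_matrix()].
#' @export
simulate_counts <- function(truth, sheet, mean_profile, dispersion = 0.01,
                            seed = NULL, size_factors = NULL, lengths = NULL) {
  sheet <- validate_sample_sheet(sheet)
  lfc <- truth$planted_lfc
  if (is.null(names(lfc))) stop("truth$planted_lfc must be named by contig")
  n_contigs <- length(lfc)
  mean_profile <- rep_len(mean_profile, n_contigs)
  dispersion <- rep_len(dispersion, n_contigs)
  if (any(mean_profile <= 0)) stop("mean_profile must be positive")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_samples <- nrow(sheet)
  if (is.null(size_factors))
    size_factors <- exp(stats::runif(n_samples, log(0.5), log(2)))
  if (is.null(lengths))
    lengths <- sample(500:5000, n_contigs, replace = TRUE)
  is_mut <- sheet$condition == "mutant"
  mu <- outer(mean_profile, size_factors) *
    2^(outer(lfc, as.numeric(is_mut)))
  counts <- matrix(0, n_contigs, n_samples,
                   dimnames = list(names(lfc), sheet$sample_id))
  pois <- dispersion == 0
  for (s in seq_len(n_samples)) {
    counts[pois, s] <- stats::rpois(sum(pois), mu[pois, s])
    if (any(!pois))
      counts[!pois, s] <- stats::rnbinom(sum(!pois), mu = mu[!pois, s],
                                         size = 1 / dispersion[!pois])
  }
  count_matrix(counts, lengths)
}

#' Simulate a complete truth-known differential-expression experiment
#'
#' Convenience wrapper that builds a sample sheet, plants log2 fold changes
#' disproportionately into a designated "gut-enriched" contig subset, and
#' draws the count matrix with [simulate_counts()].
#'
#' @param n_contigs total contigs.
#' @param n_gut number of contigs designated gut-enriched.
#' @param p_de_gut probability a gut contig carries a planted effect.
#' @param p_de_other probability a non-gut contig carries a planted effect.
#' @param lfc magnitude of planted log2 fold changes (sign drawn at random).
#' @param mean_range range of baseline means, drawn log-uniformly.
#' @param dispersion NB dispersion (see [simulate_counts()]).
#' @param n_mutant,n_control samples per condition.
#' @param batch batch labels (recycled across samples).
#' @param seed integer seed.
#' @return A list: `counts` ([count_matrix()]), `sheet` (sample sheet), and
#'   `truth` with `planted_lfc`, `de_contigs`, `gut_contigs`.
#' @export
simulate_experiment <- function(n_contigs = 500, n_gut = 50, p_de_gut = 0.5,
                                p_de_other = 0.02, lfc = 2,
                                mean_range = c(200, 2000), dispersion = 0.01,
                                n_mutant = 3, n_control = 3, batch = "42h",
                                seed = 1) {
  set.seed(seed)
  contigs <- sprintf("contig_%04d", seq_len(n_contigs))
  gut <- contigs[seq_len(n_gut)]
  p_de <- ifelse(contigs %in% gut, p_de_gut, p_de_other)
  is_de <- stats::runif(n_contigs) < p_de
  planted <- ifelse(is_de, sample(c(-lfc, lfc), n_contigs, replace = TRUE), 0)
  names(planted) <- contigs
  sheet <- data.frame(
    sample_id = c(sprintf("mut_%d", seq_len(n_mutant)),
                  sprintf("ctl_%d", seq_len(n_control))),
    condition = c(rep("mutant", n_mutant), rep("control", n_control)),
    batch = batch,
    pool_size = 100L, stringsAsFactors = FALSE)
  means <- exp(stats::runif(n_contigs, log(mean_range[1]), log(mean_range[2])))
  truth <- list(planted_lfc = planted, de_contigs = contigs[is_de],
                gut_contigs = gut)
  counts <- simulate_counts(truth, sheet, means, dispersion)
  list(counts = counts, sheet = sheet, truth = truth)
}

#' Simulate a tissue expression matrix with certified gut-enriched genes
#'
#' Builds a gene-by-tissue matrix of mean expression in which a planted gene
#' subset satisfies the gut-enrichment rule with margin — gut strictly above
#' every other retained tissue, and at least `rule_k` of the `n_other_tissues`
#' others at most half (1/`fold`) of the gut level — while every non-planted
#' gene violates at least one clause. Excluded tissues (eggs, embryos) get
#' arbitrary values, sometimes above gut, so the exclusion is exercised.
#'
#' The output is certified: the classifier is run on it before returning and
#' must recover exactly the planted set.
#'
#' @param n_genes total genes.
#' @param n_enriched number of planted gut-enriched genes.
#' @param n_other_tissues number of non-gut adult tissues (default 8).
#' @param seed integer seed.
#' @param fold fold margin of the rule (default 2).
#' @param rule_k minimum number of other tissues the fold clause must hold in
#'   (default 7).
#' @return A list: `matrix` (gene x tissue), `target` ("gut"), `excluded`
#'   (c("eggs", "embryos")), `truth` (planted gene ids).
#' @export
simulate_tissue_matrix <- function(n_genes, n_enriched, n_other_tissues = 8,
                                   seed = NULL, fold = 2, rule_k = 7) {
  stopifnot(n_enriched <= n_genes, n_other_tissues >= 1,
            rule_k <= n_other_tissues)
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  tissues <- c("gut", sprintf("tissue_%d", seq_len(n_other_tissues)))
  m <- matrix(0, n_genes, length(tissues), dimnames = list(genes, tissues))
  slack <- n_other_tissues - rule_k  # tissues allowed above gut/fold
  for (i in seq_len(n_genes)) {
    g <- exp(stats::rnorm(1, log(200), 0.7))
    other <- stats::runif(n_other_tissues, 0, 0.85 * g / fold)
    if (i <= n_enriched) {
      # use part of the k-of-m slack half the time, keeping a strict margin
      n_near <- if (slack > 0 && stats::runif(1) < 0.5)
        sample.int(slack, 1) else 0L
      if (n_near > 0)
        other[seq_len(n_near)] <- stats::runif(n_near, 1.1 * g / fold, 0.9 * g)
    } else {
      mode <- sample(c("dominated", "too_many_near"), 1)
      if (mode == "dominated") {
        other[1L] <- g * stats::runif(1, 1.1, 2)
      } else {
        n_near <- slack + 1L
        other[seq_len(n_near)] <- stats::runif(n_near, 1.1 * g / fold, 0.9 * g)
      }
    }
    m[i, ] <- c(g, other)
  }
  # excluded tissues may exceed gut freely; the classifier must ignore them
  excl <- cbind(eggs = m[, "gut"] * stats::runif(n_genes, 0, 3),
                embryos = exp(stats::rnorm(n_genes, log(100), 1)))
  m <- cbind(m, excl)
  out <- list(matrix = m, target = "gut", excluded = c("eggs", "embryos"),
              truth = genes[seq_len(n_enriched)])
  got <- classify_gut_enriched(m, target = "gut",
                               excluded = c("eggs", "embryos"),
                               fold = fold, rule_k = rule_k)$genes
  if (!setequal(got, out$truth))
    stop("internal error: tissue matrix failed certification")
  out
}

#' Synthetic allele-junction sequences for a small deletion
#'
#' A fixed, synthetic pair of discriminating sequences emulating a TALEN
#' deletion allele: the wild-type sequence carries the deleted bases with
#' `flank` nt of context either side; the mutant sequence is the deletion
#' junction with the same flanks. Neither is a substring of the other (on
#' either strand), so exact containment classifies a read unambiguously.
#'
#' @param flank flank length in nt either side of the deletion (default 15).
#' @return An `allele_junctions` object; see [allele_junctions()].
#' @export
default_junctions <- function(flank = 15) {
  stopifnot(flank >= 10, flank <= 25)
  left <- "GATTACAGCTAGCTAACCGGTTAAC"   # synthetic 25 nt context
  right <- "TTGGCCAATCGCGCGATATCCGTAG"  # synthetic 25 nt context
  deleted <- "CTGCAGG"                  # synthetic 7 nt deletion
  l <- substr(left, nchar(left) - flank + 1, nchar(left))
  r <- substr(right, 1, flank)
  allele_junctions(wt = paste0(l, deleted, r), mut = paste0(l, r),
                   flank = flank)
}

#' Construct and validate an allele-junction pair
#'
#' @param wt wild-type discriminating sequence (deleted bases plus flanks).
#' @param mut mutant discriminating sequence (deletion junction plus flanks).
#' @param flank flank length in nt recorded for provenance.
#' @return A list of class `allele_junctions` with elements `wt`, `mut`,
#'   `flank`.
#' @export
allele_junctions <- function(wt, mut, flank = 15) {
  wt <- toupper(wt); mut <- toupper(mut)
  if (!grepl("^[ACGT]+$", wt) || !grepl("^[ACGT]+$", mut))
    stop("junction sequences must be over {A,C,G,T}")
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (a in c(wt, rc(wt))) for (b in c(mut, rc(mut)))
    if (grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE))
      stop("junction sequences must not be substrings of each other ",
           "(on either strand)")
  structure(list(wt = wt, mut = mut, flank = flank),
            class = "allele_junctions")
}

#' Simulate allele-discriminating reads from a genotyped pool
#'
#' With `w = 2 n_wt + n_het` wild-type allele copies among `2 n` total, and an
#' allele expression bias `beta` (mutant-allele expression relative to wild
#' type), the expected wild-type read fraction is
#' `f = w / (w + beta * (2 n - w))`. Classified read counts are binomial at
#' that fraction; `error_rate` turns reads unclassifiable.
#'
#' @param pool a one-row pool composition (from [simulate_cross_pools()]) or
#'   a list with `pool_id`, `n_embryos`, `n_wt`, `n_het`, `n_hom`.
#' @param depth total reads covering the allele junction.
#' @param beta mutant-allele expression bias (> 0). 1 means both alleles are
#'   expressed equally; ~0.1 emulates strong silencing of the mutant allele,
#'   as when heterozygote pools show almost only wild-type reads.
#' @param error_rate probability a read is unclassifiable.
#' @param seed integer seed.
#' @param as_fastq if `TRUE`, also write a FASTQ file of reads embedding the
#'   junction sequences and return its path.
#' @param junctions an [allele_junctions()] pair (FASTQ mode).
#' @param path FASTQ output path (FASTQ mode); `.gz` suffix compresses.
#' @param read_length read length in nt (FASTQ mode), >= junction length.
#' @return A `pool_allele_counts` list: `pool_id`, `reads_wt`, `reads_mut`,
#'   `reads_total`, `n_unclassified`, `n_embryos`, `beta`, `error_rate`, and
#'   `fastq` (path or `NA`).
#' @export
simulate_allele_reads <- function(pool, depth, beta = 1, error_rate = 0,
                                  seed = NULL, as_fastq = FALSE,
                                  junctions = default_junctions(),
                                  path = tempfile(fileext = ".fastq"),
                                  read_length = 100) {
  stopifnot(depth >= 1, beta > 0, error_rate >= 0, error_rate < 1)
  n <- pool$n_embryos
  stopifnot(pool$n_wt + pool$n_het + pool$n_hom == n)
  if (!is.null(seed)) set.seed(seed)
  w <- 2 * pool$n_wt + pool$n_het
  f <- w / (w + beta * (2 * n - w))
  n_unclass <- stats::rbinom(1, depth, error_rate)
  n_class <- depth - n_unclass
  reads_wt <- stats::rbinom(1, n_class, f)
  reads_mut <- n_class - reads_wt
  out <- pool_allele_counts(pool_id = as.character(pool$pool_id),
                            reads_wt = reads_wt, reads_mut = reads_mut,
                            n_unclassified = n_unclass, n_embryos = n,
                            beta = beta, error_rate = error_rate)
  if (as_fastq) {
    alleles <- c(rep(junctions$wt, reads_wt), rep(junctions$mut, reads_mut),
                 rep("", n_unclass))
    alleles <- sample(alleles)
    seqs <- vapply(alleles, function(core) {
      pad <- read_length - nchar(core)
      lead <- sample.int(pad + 1L, 1L) - 1L
      s <- paste0(rand_dna(lead), core, rand_dna(pad - lead))
      if (stats::runif(1) < 0.5)
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      s
    }, character(1), USE.NAMES = FALSE)
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("%s_read_%06d", out$pool_id, seq_along(reads))
    quals <- Biostrings::BStringSet(strrep("I", read_length)[rep(1, length(reads))])
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals,
                                compress = grepl("\\.gz$", path))
    out$fastq <- path
  }
  out
}

rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Per-pool allele read counts
#'
#' @param pool_id pool identifier.
#' @param reads_wt,reads_mut classified read counts per allele.
#' @param n_unclassified reads matching neither or both junctions.
#' @param n_embryos embryos in the pool.
#' @param beta assumed mutant-allele expression bias.
#' @param error_rate assumed read misclassification probability.
#' @return A list of class `pool_allele_counts`; `reads_total` is the
#'   classified total `reads_wt + reads_mut`.
#' @export
pool_allele_counts <- function(pool_id, reads_wt, reads_mut,
                               n_unclassified = 0, n_embryos, beta = 1,
                               error_rate = 0) {
  stopifnot(reads_wt >= 0, reads_mut >= 0, n_embryos >= 1, beta > 0)
  structure(list(pool_id = pool_id, reads_wt = reads_wt,
                 reads_mut = reads_mut,
                 reads_total = reads_wt + reads_mut,
                 n_unclassified = n_unclassified,
                 n_embryos = n_embryos, beta = beta,
                 error_rate = error_rate, fastq = NA_character_),
            class = "pool_allele_counts")
}
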