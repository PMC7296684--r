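test_that("median-of-ratios size factors: identity, hand case, equivariance", {
  m <- matrix(c(5, 9, 5, 9, 5, 9), 2, 3,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_equal(unname(size_factors(m)), c(1, 1, 1))

  # two contigs with counts (2, 8) across two samples: geomean 4 per contig,
  # ratios 0.5 and 2
  m2 <- matrix(c(2, 2, 8, 8), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(size_factors(m2)), c(0.5, 2))

  # scaling one sample's column by c scales its factor relative to the
  # others by exactly c (each contig's geometric mean shifts by c^(1/S),
  # so only relative factors are equivariant)
  set.seed(1)
  m3 <- matrix(rpois(40, 50) + 1, 8, 5,
               dimnames = list(letters[1:8], paste0("s", 1:5)))
  sf <- size_factors(m3)
  m3c <- m3; m3c[, 2] <- m3c[, 2] * 3
  sfc <- size_factors(m3c)
  expect_equal(unname((sfc[2] / sfc[1]) / (sf[2] / sf[1])), 3,
               tolerance = 1e-10)
  expect_equal(unname(sfc[2] / sf[2]), 3^(4 / 5), tolerance = 1e-10)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  m <- matrix(rnbinom(600, mu = 100, size = 5), 100, 6,
              dimnames = list(sprintf("c%d", 1:100), sprintf("s%d", 1:6)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("FPKM: unit case, depth invariance, formula recomputation", {
  counts <- matrix(c(10, 1e6 - 10, 20, 2e6 - 20), 2, 2,
                   dimnames = list(c("c1", "c2"), c("s1", "s2")))
  cm <- count_matrix(counts, lengths = c(1000, 1000))
  fk <- fpkm(cm)
  expect_equal(fk["c1", "s1"], 10)  # count 10, 1 kb, library 1e6
  # doubling all counts of a sample leaves its FPKM column unchanged
  cm2 <- count_matrix(cbind(counts[, 1, drop = FALSE] * 2,
                            counts[, 2, drop = FALSE]), c(1000, 1000))
  expect_equal(fpkm(cm2)[, 1], fk[, 1])

  set.seed(3)
  counts <- matrix(rpois(15, 200) + 1, 5, 3,
                   dimnames = list(paste0("c", 1:5), paste0("s", 1:3)))
  lens <- c(500, 1000, 1500, 2000, 2500)
  cm3 <- count_matrix(counts, lens)
  direct <- counts / ((lens / 1e3) %o% (colSums(counts) / 1e6))
  expect_equal(fpkm(cm3), direct)
})

test_that("BH adjustment matches step-up hand computation and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  p <- runif(50)
  adj <- bh_adjust(p)
  # independent step-up: sort, p_(i) * m / i, cumulative min from the top
  o <- order(p)
  stepup <- rev(cummin(rev(p[o] * 50 / seq_len(50))))
  expect_equal(adj[o], pmin(stepup, 1))
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("nb_test returns the null identity on identical groups", {
  counts <- matrix(rep(c(40, 7, 0), 6), 3, 6,
                   dimnames = list(c("a", "b", "z"),
                                   c(paste0("mut_", 1:3), paste0("ctl_", 1:3))))
  fx <- list(cm = make_cm(counts), sheet = make_sheet())
  res <- nb_test(fx$cm, fx$sheet)
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
})

test_that("nb_test agrees with the exact Poisson conditional test in the zero-dispersion limit", {
  set.seed(42)
  n <- 200
  mu <- exp(runif(n, log(20), log(2000)))
  lfc <- rnorm(n, 0, 1)
  counts <- t(sapply(seq_len(n), function(i)
    c(rpois(3, mu[i] * 2^lfc[i]), rpois(3, mu[i]))))
  colnames(counts) <- c(paste0("mut_", 1:3), paste0("ctl_", 1:3))
  rownames(counts) <- sprintf("c%03d", seq_len(n))
  fx <- list(cm = make_cm(counts), sheet = make_sheet())
  res <- nb_test(fx$cm, fx$sheet)
  # binomial conditional test given the totals, at the mutant share of the
  # effective (normalised) library — the exact Poisson two-sample oracle
  sf <- size_factors(fx$cm)
  p0 <- sum(sf[1:3]) / sum(sf)
  p_exact <- vapply(seq_len(n), function(i) {
    s_mut <- sum(counts[i, 1:3]); s_ctl <- sum(counts[i, 4:6])
    stats::binom.test(s_mut, s_mut + s_ctl, p0)$p.value
  }, numeric(1))
  # concordance is capped slightly below 1 by the noise of the per-contig
  # moment dispersion estimate, which the exact test does not carry
  expect_gt(cor(res$p_value, p_exact, method = "spearman"), 0.98)
})

test_that("stratified analysis combines batches by inverse variance", {
  set.seed(5)
  # plant the effect in a minority of contigs so normalisation cannot
  # absorb it
  planted <- c(rep(1, 20), rep(0, 80))
  fx <- make_two_group_cm(mu = rep(300, 100), lfc = planted, n_mut = 4,
                          n_ctl = 4, dispersion = 0.01)
  fx$sheet$batch <- rep(c("34h", "42h"), 4)
  pooled <- nb_test(fx$cm, fx$sheet, stratify_by_batch = TRUE)
  expect_true(all(is.finite(pooled$log2fc)))
  expect_equal(unique(pooled$df), 4)  # (2+2-2) per batch, two batches
  # the planted effect survives stratification, the null contigs stay flat
  expect_gt(mean(pooled$log2fc[1:20]), 0.7)
  expect_lt(median(pooled$p_value[1:20]), 0.05)
  expect_lt(abs(mean(pooled$log2fc[21:100])), 0.15)
})

test_that("the DEG filter is a strict pure predicate", {
  res <- data.frame(contig_id = c("a", "b", "c", "d"),
                    log2fc = c(0.6, 0.5, -0.8, 2),
                    p_adjusted = c(0.01, 0.001, 0.04, 0.05),
                    fpkm_mutant = c(3, 100, 1, 50),
                    fpkm_control = c(0.5, 100, 2.5, 50),
                    stringsAsFactors = FALSE)
  # b fails |lfc| > 0.5 (boundary), d fails padj < 0.05 (boundary)
  expect_equal(apply_deg_filter(res), c("a", "c"))
  # boundary FPKM: exactly 2 in the best condition fails the strict rule
  res$fpkm_control[1] <- res$fpkm_mutant[1] <- 2
  expect_equal(apply_deg_filter(res), "c")
})

test_that("passes_filter is reproduced exactly by independent recomputation", {
  sim <- simulate_experiment(n_contigs = 300, seed = 6)
  res <- dge_analysis(sim$counts, sim$sheet)
  manual <- abs(res$log2fc) > 0.5 & res$p_adjusted < 0.05 &
    pmax(res$fpkm_mutant, res$fpkm_control) > 2
  expect_identical(res$passes_filter, manual)
  expect_setequal(apply_deg_filter(res), res$contig_id[manual])
})

test_that("PCA QC flags a planted outlier and ignores duplicated samples", {
  base <- rpois(600, 100)
  counts <- matrix(rep(base, 4), 600, 4,
                   dimnames = list(sprintf("c%03d", 1:600),
                                   c("mut_1", "mut_2", "ctl_1", "ctl_2")))
  sheet <- make_sheet(2, 2)
  qc <- pca_qc(count_matrix(counts, rep(1000, 600)), sheet)
  expect_length(qc$flagged, 0)

  set.seed(7)
  fx <- make_two_group_cm(mu = exp(runif(600, log(50), log(1000))),
                          n_mut = 3, n_ctl = 3)
  shifted <- fx$cm$counts
  shifted[, "ctl_2"] <- rpois(600, exp(runif(600, log(50), log(1000))))
  qc2 <- pca_qc(count_matrix(shifted, fx$cm$lengths), fx$sheet)
  expect_true("ctl_2" %in% qc2$flagged)
})

test_that("PC1 separates planted batches", {
  set.seed(8)
  n <- 400
  muA <- exp(runif(n, log(50), log(1000)))
  muB <- muA * 2^rnorm(n, 0, 1)  # batch-specific expression profile
  counts <- cbind(replicate(3, rpois(n, muA)), replicate(3, rpois(n, muB)))
  dimnames(counts) <- list(sprintf("c%03d", 1:n),
                           c("mut_1", "ctl_1", "mut_2", "ctl_2", "mut_3",
                             "ctl_3"))
  sheet <- data.frame(sample_id = colnames(counts),
                      condition = rep(c("mutant", "control"), 3),
                      batch = c("A", "A", "A", "B", "B", "B"),
                      pool_size = 100L, stringsAsFactors = FALSE)
  qc <- pca_qc(count_matrix(counts, rep(1000, n)), sheet)
  pc1 <- qc$coords$PC1
  batch <- qc$coords$batch
  # silhouette of the batch split on PC1
  sil <- vapply(seq_along(pc1), function(i) {
    same <- batch == batch[i]; same[i] <- FALSE
    a <- mean(abs(pc1[i] - pc1[same]))
    b <- mean(abs(pc1[i] - pc1[batch != batch[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})
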