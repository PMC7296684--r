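# parahoxpipe

Analysis toolkit for pooled-embryo RNA-seq of ParaHox (*Pdx*/*Cdx*) knockout
lines, the design used to study gut regionalisation in amphioxus and similar
systems. In these experiments heterozygous carriers are intercrossed,
offspring segregate 1:2:1, and embryos are sorted by phenotype into mutant
and sibling-control **pools** of ~100–300 individuals before sequencing. The
package covers the computational arc of such a study:

* **Differential expression** on contig-level counts: median-of-ratios
  normalisation, a per-contig negative-binomial Wald test with a
  finite-replicate t reference, Benjamini–Hochberg adjustment, and the
  strict filter |log2FC| > 0.5 ∧ adjusted p < 0.05 ∧ FPKM > 2 in at least
  one condition; PCA-based outlier screening.
* **Gut-enrichment classification**: a gene is gut-enriched when its mean
  expression in gut strictly exceeds every other adult tissue (eggs and
  embryos excluded) and is ≥2× that of at least 7 of the 8 other tissues;
  transfer to assembly contigs through a BLAST outfmt-6 hit table
  (any hit at e ≤ 1e-70).
* **Set-overlap enrichment** of DEGs against gut-enriched contigs:
  hypergeometric upper tail P(X ≥ x), X ~ Hypergeom(|U|, |A|, |B|), with a
  permutation cross-check.
* **Hox colinearity**: OLS of log2 fold change on paralog-group index with
  t and permutation p-values — a negative slope is the colinear signature.
* **Genotype auditing of pools**: a two-category Mendelian chi-square, exact
  junction-sequence read counting from FASTQ, and maximum-likelihood
  deconvolution of pool composition — with k of n embryos heterozygous, the
  expected wild-type read fraction is f(k) = k / (k + β(2n − k)), and k̂
  maximises the binomial likelihood of the observed allele counts.
* **Synthetic data with known truth** for every stage: cross pools with
  contamination, NB counts with planted fold changes concentrated in a gut
  set, certified tissue matrices, and allele-junction reads (counts or
  FASTQ).

## Worked example

```r
library(parahoxpipe)

# simulate a truth-known experiment: 500 contigs, 50 of them gut-enriched,
# effects planted preferentially into the gut set; 3 mutant vs 3 control pools
sim <- simulate_experiment(n_contigs = 500, n_gut = 50, p_de_gut = 0.5,
                           p_de_other = 0.02, seed = 42)

# differential expression with the strict filter
res <- dge_analysis(sim$counts, sim$sheet)
deg <- apply_deg_filter(res)
length(deg)
#> [1] 29
head(res[res$passes_filter, c("contig_id", "base_mean", "log2fc", "p_adjusted",
                              "fpkm_mutant", "fpkm_control")], 3)
#>      contig_id base_mean   log2fc  p_adjusted fpkm_mutant fpkm_control
#> 3  contig_0003  3197.150 1.988277 0.008528103    3534.993     953.5877
#> 8  contig_0008  2725.221 2.027915 0.003286492   18069.894    4745.5494
#> 11 contig_0011  1195.493 1.848706 0.019793498    1310.670     389.6558

# are the DEGs enriched for gut contigs?
en <- overlap_enrichment(sim$truth$gut_contigs, deg, universe = res$contig_id,
                         n_perm = 10000, seed = 1)
unlist(en[c("overlap", "expected", "pct_of_b", "p_hyper", "p_perm")])
#>      overlap     expected     pct_of_b      p_hyper       p_perm
#> 1.900000e+01 2.900000e+00 6.551724e+01 2.903871e-14 9.999000e-05

# Mendelian ratio of genotyped embryos: 18 homozygotes of 96
unlist(mendelian_chisq(18, 96, 1/4)[c("chi2", "p_value")])
#>      chi2   p_value
#> 2.0000000 0.1572992

# how many heterozygotes hide in a mutant pool of 20 with 4.8% wild-type reads?
fit <- infer_pool_heterozygotes(pool_allele_counts("pool1", 480, 9520,
                                                   n_embryos = 20))
c(k_hat = fit$k_hat, support = fit$support)
#>   k_hat support
#>       2       2
```

Reading the output: 29 contigs pass the filter, of which 19 are
gut-enriched against 2.9 expected by chance (66% of the DEG set,
hypergeometric p ≈ 3e-14) — the planted disproportionate effect on gut
genes is recovered. The genotype table 18/96 is compatible with Mendelian
1:2:1 segregation (χ² = 2.0, p = 0.157), and a 4.8% wild-type read fraction
in a pool of 20 pins the heterozygote count at 2 with the likelihood
support confined to {2}.

A command-line wrapper with the same stages (`simulate`, `dge`, `gutclass`,
`maphits`, `enrich`, `hox`, `pooldecon`, `chisq`, `qc`) is installed at
`inst/cli/parahoxpipe`; each subcommand writes TSV outputs plus a JSON
summary and is bit-reproducible given `--seed`.

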