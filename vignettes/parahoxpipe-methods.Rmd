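---
title: "Methods: pooled-embryo mutant transcriptomics with parahoxpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-embryo mutant transcriptomics with parahoxpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parahoxpipe)
```

# The experimental design this package models

ParaHox genes (*Gsx*, *Pdx*, *Cdx*) pattern the developing gut. In a
cephalochordate knockout study of this kind, heterozygous carriers of a
frameshift allele are intercrossed, so offspring segregate 1:2:1
(wild type : heterozygous : homozygous mutant). Because only homozygotes show
a visible phenotype, embryos are sorted by eye into a "mutant" pool
(homozygotes, plus an unknown small number of miscalled siblings) and a
"control" pool (wild types and heterozygotes, 1:2 in expectation). Each
sequencing library is therefore a pool of tens to hundreds of embryos, not an
individual.

Three analytical consequences drive the package design:

1. **Differential expression is pooled-vs-pooled.** Replicates are pools of
   ~100-300 sibling embryos, which averages out embryo-to-embryo biological
   variability; replicate noise is closer to technical than to individual
   biological variation. Replicate numbers are tiny (2-3 per condition).
2. **Pool purity must be audited from the reads.** Reads covering the
   deletion junction discriminate the two alleles, so the genotype
   composition of a pool is estimable from the wild-type read fraction.
3. **Downstream claims are set-level.** The biological conclusions rest on
   whether differentially expressed contigs are enriched for gut-associated
   genes, and whether Hox genes respond colinearly.

# Differential expression

## Normalisation and effect size

Size factors are median-of-ratios: for sample $s$,
$\hat{f}_s = \mathrm{median}_{c}\, y_{cs} / (\prod_{s'} y_{cs'})^{1/S}$
over contigs with an all-positive row. Counts may be fractional (fragment
counting with multi-mapping assignment); they are normalised as given, and
rounded to the nearest integer only where a count model is fitted.

The per-contig effect is
$\widehat{\mathrm{lfc}} = \log_2(\bar{y}^{mut} + \tfrac12) -
\log_2(\bar{y}^{ctl} + \tfrac12)$ on normalised group means. The 0.5
pseudocount bounds the estimate when one group is all-zero; it matters only
for very low counts, far below the expression floor of the filter.

## The test and its reference distribution

Dispersion is estimated per contig by method of moments on normalised
counts, $\hat\alpha = \max(0, (s^2 - \bar{y})/\bar{y}^2)$ with the pooled
within-group variance $s^2$, giving NB variance $\mu + \hat\alpha\mu^2$
(Poisson floor at $\hat\alpha = 0$). The Wald statistic is
$\widehat{\mathrm{lfc}} / \widehat{SE}$ with the delta-method standard
error. No information is shared across contigs: each contig's test is
self-contained.

P-values use a **t reference with $n_1 + n_2 - 2$ degrees of freedom**
rather than the asymptotic normal. With 2-3 replicates per group the
plug-in dispersion is estimated from ~4 residual degrees of freedom, and
treating the resulting statistic as standard normal is sharply
anti-conservative (in our null simulations at 3v3, the normal reference
rejects ~12% at nominal 5%, and the realised FDR after Benjamini-Hochberg
exceeds 25%). The t reference accounts for the estimator noise the same way
the classic two-sample t-test does, and calibrates the null rejection rate
to within Monte-Carlo error of the nominal level across the regimes we
simulate. With one sample per group the dispersion is unidentifiable; the
test falls back to a Poisson-variance normal reference and warns.

Two honest limitations of the per-contig design:

* **Power at few replicates and moderate dispersion.** A 4 degrees of
  freedom t reference has heavy tails, so at dispersion ~0.05 and 3v3 even
  4-fold planted changes reach genome-wide significance only ~half the
  time. Methods that share dispersion across contigs (DESeq2, edgeR) buy
  their small-sample power exactly there; per-contig estimation cannot,
  and we prefer calibrated p-values over optimistic ones. At the
  dispersion levels characteristic of large sibling pools (~0.01, see
  below) sensitivity for 4-fold changes exceeds 0.95.
* **Poisson-limit concordance.** On zero-dispersion data, ranks of our
  p-values agree with the exact binomial conditional (two-sample Poisson)
  test at Spearman ~0.98-0.99; the residual discordance is the sampling
  noise of $\hat\alpha$ itself, which an exact test does not carry.

## Batches

With `stratify_by_batch = TRUE` the test runs within each batch
(e.g. developmental stage) and combines per-batch fold changes by
inverse-variance weighting; degrees of freedom add. This keeps the model
closed-form instead of introducing a GLM with covariates, at the cost of not
estimating a batch main effect; the PCA QC view is the intended instrument
for deciding whether stratification is needed.

## The filter

A contig is called differentially expressed iff all three hold, strictly:

* $|\mathrm{lfc}| > 0.5$ (log2),
* Benjamini-Hochberg adjusted $p < 0.05$,
* FPKM $> 2$ in at least one condition.

"FPKM in a condition" is the mean of per-sample FPKM over that condition's
samples (`fpkm_mode = "condition_mean"`); whether the original rule meant
condition means or single samples is ambiguous, so the alternative
(`"max_sample"`) is a switch. FPKM uses raw (unrounded) counts and raw
library sizes. Boundary values fail: a contig at exactly 0.5 log2 or
exactly 2 FPKM is not called.

## PCA QC

Outlier screening mimics how a pooled study drops a misbehaving library:
PCA of $\log_2(\text{normalised count} + 1)$ over the 500 most variable
contigs, flagging samples farther than 3x the median within-condition
distance from their condition centroid in the PC1/PC2 plane. The threshold
is deliberately loose — it flags gross outliers (swapped or degraded
libraries), not subtle shifts.

# Gut-enrichment classification and transfer

A gene is **gut-enriched** when, over adult tissues with eggs and embryos
excluded: (1) its mean expression in gut strictly exceeds every other
tissue, and (2) gut is at least 2-fold above at least 7 of the 8 other
tissues. Edge policy, made explicit because the phrasing leaves it open:
"higher than" is strict, "at least double" is non-strict ($\ge$), and a
zero denominator satisfies the fold clause when the gut value is positive.
The rule uses only within-gene ratios and orderings, so it is invariant to
the expression unit and to global rescaling.

Transfer to assembly contigs is **any-hit**: a contig qualifies if any
gut-enriched gene hits it at BLAST e-value $\le 10^{-70}$. One gene may
mark several contigs (superTranscript assemblies split genes across
contigs), and a contig needs only one qualifying hit.

# Overlap enrichment

The question "are DEGs disproportionately gut-enriched?" is answered with
the hypergeometric upper tail $P(X \ge x)$, $X \sim$
Hypergeom($|U|, |A|, |B|$), plus a permutation cross-check that redraws
$|B|$ contigs from the universe (with the +1 small-sample correction). The
universe is the set of **tested** contigs, conditioning on testability;
using the full assembly instead would inflate significance and is not
offered as a default.

# Hox colinearity

Colinearity is summarised as ordinary least squares of per-gene log2 fold
change on paralog-group index (1 = anterior-most). A negative slope is the
colinear-like signature: anterior groups up, posterior groups down. Because
only ~7 points enter, the t-test on the slope is complemented by a
permutation p-value (shuffling fold changes across indices), which is the
one we recommend reporting.

# Pool genotype deconvolution

With $n$ embryos of which $k$ are heterozygous and the rest homozygous
mutant, the wild-type allele contributes $k$ of the $2n$ copies, and with a
mutant-allele expression bias $\beta$ (mutant transcript level relative to
wild type) the expected wild-type read fraction is
$$ f(k) = \frac{k}{k + \beta\,(2n - k)}. $$
Classified reads are modelled Binomial($R$, $f(k)$); $f$ is strictly
increasing in $k$, so the profile likelihood over $k \in \{0..n\}$ is
unimodal and the MLE unique up to boundary ties. The support interval is
$\{k : \log L(k) \ge \log L(\hat k) - 2\}$. Expectations are clamped to
$[10^{-6}, 1 - 10^{-6}]$ so $k = 0$ stays finite under stray reads; a known
misclassification rate $e$ can instead be folded in as
$f' = f(1-e) + (1-f)e$.

Read classification itself is exact substring containment of the two
discriminating junction sequences (deleted bases plus 15 nt flanks for the
wild-type allele; the deletion junction with the same flanks for the
mutant), checked on both strands. Reads matching neither or both are
excluded and tallied. No mismatches are tolerated — deterministic, with no
alignment step; at 15 nt flanks, chance matches are negligible and real
reads fail only for sequencing errors inside the window, which depresses
both alleles symmetrically.

$\beta = 1$ treats both alleles as equally expressed. The package ships a
low-$\beta$ preset intuition rather than a constant: when a knockout allele
is transcriptionally silenced in heterozygotes, control pools drift toward
pure wild-type reads ($\beta \approx 0.1$ reproduces the ~91-100% wild-type
read fractions that make read-based heterozygote counting uninformative —
the reason the method applies to crosses where both alleles are seen).

The Mendelian-ratio check is a two-category Pearson chi-square (focal class
vs rest, df = 1) of the genotyped counts against the expected proportion; a
three-class 1:2:1 test needs the full genotype breakdown, which a
focal-vs-rest count table does not carry.

# The synthetic-data generators

The generators produce inputs with known truth and the statistical
structure the analysis assumes; acceptance of the pipeline is measured
against that truth.

* **Cross pools.** Mutant pools: Binomial(pool size, miscall rate)
  contaminants, het:wt 2:1 among contaminants (the conditional Mendelian
  ratio); control pools: wt:het 1:2. Default miscall rate 0.05 — the level
  implied by 1-2 heterozygotes in a sorted pool of 20.
* **Counts.** NB with mean $\mu_c f_s 2^{\mathrm{lfc}_c \cdot
  \mathbb{1}(mutant)}$ and variance $\mu + \alpha\mu^2$. Default
  $\alpha = 0.01$: sibling pools of ~100-300 embryos average individual
  variation down to near-technical levels. Size factors are drawn
  log-uniform from $[0.5, 2]$ (library-size variation is otherwise
  unreported for such designs); baseline means log-uniform 200-2000;
  planted effects are $\pm 2$ log2 (4-fold, within the range observed for
  real gut effectors) and are planted into a designated gut-enriched
  subset at a higher rate than background, so the end-to-end enrichment
  question has a planted answer.
* **Tissue matrix.** Constructive, with margins: planted genes satisfy
  both clauses with ~10% headroom, non-planted genes violate exactly one
  clause (either dominated by another tissue, or 2-fold in too few
  tissues), and excluded tissues get values that would break the rule if
  they were not excluded. The generator re-runs the classifier before
  returning and stops if recovery is not exact, so the output is a
  certified fixture.
* **Allele reads.** Binomial read counts at $f(k)$, optionally emitted as
  FASTQ with the junction embedded at a random offset and strand in random
  sequence; an error rate diverts reads to unclassifiable.

What the generators deliberately do **not** model: GC/length biases,
positional coverage structure, isoform mixtures, base-quality error
profiles, dispersion trends over mean, and correlated contigs. Passing the
synthetic recovery tests therefore demonstrates the statistical machinery
is correct under the stated model, not that real libraries satisfy that
model.

# Validation problem sizes

The shipped checks run at: 5,000 null contigs for test calibration; 2,000
contigs (200 gut) for planted-effect recovery; 500 contigs / 50 gut for the
end-to-end enrichment property; 500 simulated pools for deconvolution
recovery; 10,000 permutations for permutation p-values; exhaustive
enumeration up to universe size 15 for the hypergeometric oracle. These
sizes give comfortable Monte-Carlo margins for every asserted bound while
keeping a full run in the order of a minute.

The published full-scale numbers for this kind of study (thousands of
gut-enriched genes and contigs classified from a public adult-tissue
expression matrix) require the external expression matrix and a blastn run
against the deposited assembly; the classifier accepts those inputs
directly (`read_tissue_matrix()`, `read_hit_table()`) but the data are not
bundled.

# Known limitations

* No GLM with arbitrary designs, no dispersion sharing, no outlier
  replacement, no independent filtering of the adjusted-p denominator —
  the test is intentionally the minimal calibrated per-contig model.
* Inverse-variance batch combination estimates a common effect across
  batches; a genuine batch-by-genotype interaction will be averaged, not
  detected.
* Junction matching is exact; heavily error-prone reads undercount both
  alleles (symmetrically, so the fraction is approximately unbiased, but
  the effective depth shrinks).
* The deconvolution assumes the pool is exactly {het, hom} for mutant
  pools; a wild-type embryo miscalled into a mutant pool contributes two
  wild-type copies and will be counted as ~2 heterozygotes.
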