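Package: parahoxpipe
Title: Pooled-Embryo Mutant Transcriptome Analysis for ParaHox Knockout Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled-embryo RNA-seq of ParaHox (Pdx/Cdx)
    knockout lines in amphioxus-style crosses. Implements median-of-ratios
    normalisation, a per-contig negative-binomial Wald test with a strict
    differential-expression filter (|log2 fold change| > 0.5, adjusted
    p < 0.05, > 2 FPKM in at least one condition), a tissue-specificity
    classifier for gut-enriched genes and its transfer to assembly contigs
    through BLAST hits, gene-set overlap enrichment (hypergeometric and
    permutation), Hox colinearity regression, Mendelian-ratio testing, and
    maximum-likelihood deconvolution of pool genotype composition from
    allele-discriminating read counts. A synthetic-data module generates
    truth-known inputs (het-by-het cross pools, negative-binomial counts with
    planted effects, certified tissue matrices, allele-junction reads) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
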