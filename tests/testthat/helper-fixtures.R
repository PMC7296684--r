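# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

make_cm <- function(counts, lengths = rep(1000, nrow(counts))) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  count_matrix(counts, lengths)
}

make_sheet <- function(n_mut = 3, n_ctl = 3, batch = "42h",
                       ids = c(sprintf("mut_%d", seq_len(n_mut)),
                               sprintf("ctl_%d", seq_len(n_ctl)))) {
  data.frame(sample_id = ids,
             condition = c(rep("mutant", n_mut), rep("control", n_ctl)),
             batch = batch, pool_size = 100L, stringsAsFactors = FALSE)
}

# Count matrix with matching sheet where control and mutant columns are drawn
# Poisson/NB around per-contig means, optionally with per-contig lfc.
make_two_group_cm <- function(mu, lfc = 0, n_mut = 3, n_ctl = 3,
                              dispersion = 0) {
  n <- length(mu)
  lfc <- rep_len(lfc, n)
  draw <- function(m) {
    if (dispersion == 0) rpois(n, m) else rnbinom(n, mu = m, size = 1 / dispersion)
  }
  ctl <- replicate(n_ctl, draw(mu))
  mut <- replicate(n_mut, draw(mu * 2^lfc))
  counts <- cbind(mut, ctl)
  colnames(counts) <- c(sprintf("mut_%d", seq_len(n_mut)),
                        sprintf("ctl_%d", seq_len(n_ctl)))
  rownames(counts) <- sprintf("c%04d", seq_len(n))
  list(cm = make_cm(counts), sheet = make_sheet(n_mut, n_ctl))
}
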