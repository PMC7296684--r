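#' Construct a contig-by-sample count matrix
#'
#' The central container of the pipeline: raw fragment counts per assembly
#' contig per sequenced embryo pool, together with contig lengths (needed for
#' FPKM). Counts may be fractional because fragment counting with
#' multi-mapping assignment distributes fragments across contigs.
#'
#' @param counts numeric matrix, contigs in rows and samples in columns, with
#'   row and column names. All values must be finite and non-negative.
#' @param lengths positive integer vector of contig lengths in nucleotides,
#'   one per row of `counts`. May be named; names must then match the rows.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (numeric matrix) and `lengths` (named numeric vector).
#' @examples
#' m <- matrix(c(10, 0, 5, 7), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("s1", "s2")))
#' cm <- count_matrix(m, lengths = c(1000, 500))
#' dim(cm$counts)
#' @export
count_matrix <- function(counts, lengths) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have row (contig) and column (sample) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate contig id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)))
    stop("counts contain non-finite values")
  if (any(counts < 0))
    stop("counts must be non-negative")
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts))
    stop("`lengths` must have one entry per contig")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("contig lengths must be >= 1 nt")
  names(lengths) <- rownames(counts)
  structure(list(counts = counts, lengths = lengths), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d contigs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("contig lengths:", min(x$lengths), "-", max(x$lengths), "nt\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by contigs and/or samples
#'
#' @param x a [count_matrix()].
#' @param i contig index (row) selector.
#' @param j sample index (column) selector.
#' @param ... unused.
#' @return A `count_matrix` restricted to the selected rows/columns.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  counts <- x$counts[i, j, drop = FALSE]
  count_matrix(counts, x$lengths[rownames(counts)])
}

#' Read a count matrix from TSV
#'
#' Expects a header row and columns: contig id, contig length (nt), then one
#' column per sample. Fractional counts are allowed.
#'
#' @param path path to a tab-separated file.
#' @return A [count_matrix()].
#' @seealso [write_count_matrix()]
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop("count matrix needs >= 3 columns (contig, length, samples): ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate contig id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  num <- df[, -1L, drop = FALSE]
  for (k in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[k]]))
    bad <- which(is.na(v) & !is.na(num[[k]]))
    if (length(bad) || anyNA(num[[k]]))
      stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                   path, c(bad, which(is.na(num[[k]])))[1L],
                   names(num)[k]))
    num[[k]] <- v
  }
  m <- as.matrix(num[, -1L, drop = FALSE])
  rownames(m) <- ids
  count_matrix(m, lengths = num[[1L]])
}

#' Write a count matrix to TSV
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(contig = rownames(x$counts),
                   length = x$lengths,
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Columns: `sample_id`, `condition` (one of "mutant"/"control"), `batch`
#' (free label, e.g. a developmental stage), `pool_size` (embryos per pool).
#'
#' @param path path to a tab-separated file with header.
#' @return A data.frame with the four columns above.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet data.frame to validate.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "condition", "batch", "pool_size")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$condition <- as.character(sheet$condition)
  sheet$batch <- as.character(sheet$batch)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!all(sheet$condition %in% c("mutant", "control")))
    stop("condition must be 'mutant' or 'control'")
  if (any(!is.finite(sheet$pool_size)) || any(sheet$pool_size < 1))
    stop("pool_size must be a positive integer")
  sheet
}

#' Write a sample sheet to TSV
#'
#' @param sheet a sample-sheet data.frame (see [read_sample_sheet()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
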