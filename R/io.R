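#' Read a BLAST tabular hit table (outfmt 6)
#'
#' Parses the standard headerless 12-column BLAST tabular dialect:
#' query id, subject id, percent identity, alignment length, mismatches,
#' gap opens, query start/end, subject start/end, e-value, bit score.
#' Here queries are genes and subjects are assembly contigs.
#'
#' @param path path to a headerless 12-column TSV. An empty file yields an
#'   empty table.
#' @return A data.frame with columns `query_gene`, `subject_contig`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`.
#' @export
read_hit_table <- function(path) {
  cols <- c("query_gene", "subject_contig", "percent_identity",
            "alignment_length", "mismatches", "gap_opens",
            "q_start", "q_end", "s_start", "s_end", "e_value", "bit_score")
  if (file.size(path) == 0) {
    df <- as.data.frame(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), cols))
    return(df)
  }
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 12)
    stop("BLAST outfmt 6 requires 12 tab-separated columns, found ",
         ncol(df), " in ", path)
  names(df) <- cols
  df$query_gene <- as.character(df$query_gene)
  df$subject_contig <- as.character(df$subject_contig)
  for (k in 3:12) df[[k]] <- as.numeric(df[[k]])
  if (any(!nzchar(df$query_gene)) || any(!nzchar(df$subject_contig)))
    stop("empty query/subject identifier in hit table")
  if (any(df$e_value < 0)) stop("negative e-value in hit table")
  df
}

#' Write a hit table in BLAST outfmt 6
#'
#' @param hits a hit-table data.frame as returned by [read_hit_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write a gene/contig set as newline-delimited text
#'
#' Blank lines and lines starting with `#` are ignored on read; the set is
#' de-duplicated preserving first occurrence.
#'
#' @param path file path.
#' @return `read_gene_set`: a character vector of identifiers.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' @rdname read_gene_set
#' @param ids character vector of identifiers.
#' @export
write_gene_set <- function(ids, path) {
  writeLines(unique(as.character(ids)), path)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML key-value file holding analysis thresholds and labels. Missing keys
#' fall back to the pipeline defaults; supplied thresholds are checked for
#' positivity and seeds for integrality.
#'
#' @param path path to a YAML file, or `NULL` for all defaults.
#' @return A named list with at least: `lfc_min`, `alpha`, `fpkm_min`,
#'   `evalue_max`, `fold`, `k_of_m`, `target_tissue`, `excluded_tissues`,
#'   `fpkm_mode` (`"condition_mean"` or `"per_sample"`), `seed`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config must be a YAML mapping: ", path)
    cfg[names(user)] <- user
  }
  for (key in c("lfc_min", "alpha", "fpkm_min", "evalue_max", "fold")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("config threshold `", key, "` must be a positive number")
  }
  if (!is.numeric(cfg$seed) || cfg$seed != as.integer(cfg$seed))
    stop("config `seed` must be an integer")
  cfg
}

default_config <- function() {
  list(lfc_min = 0.5, alpha = 0.05, fpkm_min = 2,
       evalue_max = 1e-70, fold = 2, k_of_m = c(7L, 8L),
       target_tissue = "gut",
       excluded_tissues = c("eggs", "embryos"),
       fpkm_mode = "condition_mean",
       seed = 1L)
}

# One JSON summary per TSV output so downstream consumers parse a single file.
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
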