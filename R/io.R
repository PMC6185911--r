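#' Read a count table from TSV or BIOM
#'
#' TSV follows the usual amplicon convention: first column taxon ids,
#' remaining columns samples (one column per sample). Set
#' `samples_as_rows = TRUE` if the file is already samples x taxa. BIOM
#' input (JSON dialect) is read through the biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"biom"`.
#' @param samples_as_rows for TSV: rows are samples rather than taxa.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             samples_as_rows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for BIOM input")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # observations x samples
    return(count_table(t(m)))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty table: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in count table: ", path)
  rownames(m) <- ids
  if (!samples_as_rows) m <- t(m)
  count_table(m)
}

#' Write a count table to TSV or BIOM
#'
#' Inverse of [read_count_table()]; `write` then `read` round-trips to an
#' identical table for both formats.
#'
#' @param table a [count_table()].
#' @param path output file path.
#' @param format `"tsv"` or `"biom"`.
#' @param samples_as_rows for TSV: write samples as rows.
#' @export
write_count_table <- function(table, path, format = c("tsv", "biom"),
                              samples_as_rows = FALSE) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for BIOM output")
    b <- biomformat::make_biom(t(unclass(table)))  # observations x samples
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  m <- unclass(table)
  if (!samples_as_rows) {
    out <- data.frame(taxon_id = colnames(m), t(m), check.names = FALSE)
  } else {
    out <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `group`, `habitat_class`; `location` and
#' `replicate` are optional. See [sample_metadata()] for validation rules.
#'
#' @param path file path.
#' @return a validated `sample_metadata` data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  sample_metadata(df)
}

#' Write sample metadata to TSV
#' @param meta a `sample_metadata` data.frame.
#' @param path output file path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#' @param path file path; needs a `taxon_id` column plus rank columns.
#' @return a validated `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  taxonomy_table(df)
}

#' Cross-validate a count table against sample metadata
#'
#' Lists samples present in exactly one of the two inputs. With
#' `permissive = TRUE` both objects are subset to the common samples;
#' otherwise any discrepancy is a hard error. An empty intersection is
#' always a hard error.
#'
#' @param table a [count_table()].
#' @param meta a `sample_metadata` data.frame.
#' @param permissive proceed on the intersection when the inputs disagree.
#' @return list with `table`, `meta` (possibly subset), `only_in_table`,
#'   `only_in_meta`.
#' @export
validate_pair <- function(table, meta, permissive = FALSE) {
  ts <- rownames(table)
  ms <- meta$sample_id
  common <- intersect(ts, ms)
  if (!length(common)) stop("count table and metadata share no samples")
  only_t <- setdiff(ts, ms)
  only_m <- setdiff(ms, ts)
  if ((length(only_t) || length(only_m)) && !permissive) {
    stop("sample sets disagree (set permissive = TRUE to use the intersection); ",
         "only in table: [", paste(only_t, collapse = ", "),
         "]; only in metadata: [", paste(only_m, collapse = ", "), "]")
  }
  tab2 <- table
  if (length(only_t)) tab2 <- count_table(unclass(table)[common, , drop = FALSE])
  meta2 <- meta[match(common, meta$sample_id), , drop = FALSE]
  list(table = tab2, meta = meta2,
       only_in_table = only_t, only_in_meta = only_m)
}

#' Per-species summary table from the Nha Trang Bay sponge survey
#'
#' The published per-species summary of a 19-species sponge microbiome
#' survey (Nha Trang Bay, Vietnam): replicate count, mean ZOTU richness,
#' core size, core relative abundance, species-specific and
#' seawater-shared core ZOTU counts and abundances. Shipped as a plain-text
#' fixture; used as the default template for [sim_params()] and for
#' rank-correlation checks of core size against replicate number.
#'
#' @return data.frame with one row per sponge species.
#' @export
nhatrang_summary <- function() {
  path <- system.file("extdata", "nhatrang_summary.tsv", package = "spongecore")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
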