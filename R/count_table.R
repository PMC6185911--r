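#' Construct a validated sample-by-taxon count table
#'
#' The central object of the pipeline: a samples x taxa matrix of
#' non-negative integer read counts with unique sample and taxon
#' identifiers. All downstream stages (rarefaction, core extraction,
#' seawater overlap, permutation statistics) consume this object.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns; must be
#'   non-negative integers with unique, non-empty dimnames.
#' @return an integer matrix of class `count_table`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' count_table(m)
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs sample (row) and taxon (column) names")
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("empty count table")
  dup_s <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  dup_t <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_t))
    stop("duplicate taxon id(s): ", paste(unique(dup_t), collapse = ", "))
  if (anyNA(counts)) stop("count table contains NA")
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("negative or non-integer count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  }
  zero <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero))
    stop("sample(s) with zero total reads: ", paste(zero, collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(counts, class = c("count_table", class(matrix())))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d taxa, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

is_count_table <- function(x) inherits(x, "count_table")

# strips the class so matrix maths doesn't re-trigger validation
ct_matrix <- function(x) {
  y <- unclass(x)
  storage.mode(y) <- "double"
  y
}

#' Construct validated sample metadata
#'
#' Per-sample grouping used throughout the pipeline: the source sponge
#' species (or `"seawater"`), the habitat class (HMA = high microbial
#' abundance sponge, LMA = low microbial abundance sponge, SW = seawater),
#' sampling location and replicate index. `habitat_class` is matched
#' case-insensitively; sample and taxon identifiers are case-sensitive.
#'
#' @param df data.frame with at least columns `sample_id`, `group`,
#'   `habitat_class`; optional `location` and `replicate`.
#' @return validated data.frame of class `sample_metadata` with
#'   `habitat_class` normalised to `"HMA"/"LMA"/"SW"`.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "group", "habitat_class")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  hc <- toupper(as.character(df$habitat_class))
  bad <- setdiff(unique(hc), c("HMA", "LMA", "SW"))
  if (length(bad))
    stop("unknown habitat_class value(s): ", paste(bad, collapse = ", "))
  df$habitat_class <- hc
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample id(s) in metadata: ", paste(unique(dup), collapse = ", "))
  sw_mismatch <- xor(df$group == "seawater", df$habitat_class == "SW")
  if (any(sw_mismatch))
    stop("habitat_class must be SW exactly for group 'seawater'; offending sample(s): ",
         paste(df$sample_id[sw_mismatch], collapse = ", "))
  if (is.null(df$location)) df$location <- NA_character_
  if (is.null(df$replicate)) {
    df$replicate <- stats::ave(seq_len(nrow(df)), df$group, FUN = seq_along)
  }
  if (any(df$replicate < 1)) stop("replicate index must be >= 1")
  sponge <- df[df$habitat_class != "SW", , drop = FALSE]
  n_per <- table(sponge$group)
  singletons <- names(n_per)[n_per < 2]
  if (length(singletons))
    warning("sponge group(s) with a single sample (core extraction degenerate): ",
            paste(singletons, collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Construct a validated taxonomy table
#'
#' Carries a pre-computed lineage per taxon (this package performs no
#' taxonomic assignment). Ranks are ordered broad to narrow.
#'
#' @param df data.frame with a `taxon_id` column plus any of the rank
#'   columns `domain`, `phylum`, `class`, `order`, `family`, `genus`.
#'   Missing ranks may be `NA`.
#' @return data.frame of class `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  if (is.null(df$taxon_id)) stop("taxonomy needs a taxon_id column")
  df$taxon_id <- as.character(df$taxon_id)
  dup <- df$taxon_id[duplicated(df$taxon_id)]
  if (length(dup))
    stop("duplicate taxon id(s) in taxonomy: ", paste(unique(dup), collapse = ", "))
  ranks <- intersect(taxonomic_ranks(), names(df))
  if (!length(ranks)) stop("taxonomy has no recognised rank column")
  df <- df[, c("taxon_id", ranks), drop = FALSE]
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

taxonomic_ranks <- function() c("domain", "phylum", "class", "order", "family", "genus")

# group -> sample ids helper used by most stages
samples_of <- function(meta, group) {
  ids <- meta$sample_id[meta$group == group]
  if (!length(ids)) stop("unknown group: ", group)
  ids
}

water_samples <- function(meta) meta$sample_id[meta$habitat_class == "SW"]

# evaluate an expression under a temporary, seeded RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
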