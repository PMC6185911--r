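#' Rarefy a count table to even depth
#'
#' Random subsampling without replacement (multivariate hypergeometric draw
#' per sample, via [vegan::rrarefy()]) so that every retained sample has
#' exactly `depth` reads. Samples with fewer than `depth` reads are dropped
#' (default) or raise an error. One seeded draw; the seed should be recorded
#' alongside any results.
#'
#' @param table a [count_table()].
#' @param depth target reads per sample (the survey this package was built
#'   around used 41000).
#' @param seed integer seed for the draw.
#' @param drop_below drop samples shallower than `depth` (default) instead
#'   of erroring.
#' @return a [count_table()] whose row sums all equal `depth`, with an
#'   attribute `dropped` listing removed samples.
#' @export
rarefy <- function(table, depth = 41000, seed = NULL, drop_below = TRUE) {
  stopifnot(is_count_table(table))
  if (depth < 1) stop("depth must be >= 1")
  totals <- rowSums(table)
  shallow <- rownames(table)[totals < depth]
  if (length(shallow) == nrow(table))
    stop("all samples have fewer than ", depth, " reads")
  if (length(shallow) && !drop_below)
    stop("sample(s) below depth ", depth, ": ", paste(shallow, collapse = ", "))
  keep <- unclass(table)[totals >= depth, , drop = FALSE]
  # vegan warns heuristically when a table has no singleton counts; counts
  # here are validated integers, so that plausibility nudge is noise
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(keep, depth),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  out <- count_table(out)
  attr(out, "dropped") <- shallow
  attr(out, "depth") <- depth
  out
}

#' Convert counts to relative abundances
#'
#' @param table a [count_table()] (every sample must have > 0 reads, which
#'   the constructor guarantees).
#' @return samples x taxa matrix of class `abundance_table`; rows sum to 1.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(is_count_table(table))
  m <- ct_matrix(table)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("zero-sum sample(s)")
  out <- sweep(m, 1L, rs, "/")
  structure(out, class = c("abundance_table", class(matrix())))
}

#' Aggregate taxa to a taxonomic rank
#'
#' Sums counts (or relative abundances) of taxa sharing the same label at
#' `rank`. Taxa without an assignment at that rank go to `"Unclassified"`.
#' With `proteobacteria_to_class = TRUE` (the usual convention for
#' phylum-level sponge microbiome summaries), taxa whose phylum is
#' Proteobacteria are labelled by their class instead, so e.g. Alpha-,
#' Beta- and Gammaproteobacteria appear side by side with other phyla.
#'
#' @param table a [count_table()] or `abundance_table`.
#' @param taxonomy a [taxonomy_table()].
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @param proteobacteria_to_class split Proteobacteria by class when
#'   aggregating at phylum level.
#' @return matrix (same class as the input) at the requested rank; per-sample
#'   totals are conserved exactly.
#' @export
aggregate_taxa <- function(table, taxonomy, rank = "phylum",
                           proteobacteria_to_class = FALSE) {
  if (!rank %in% taxonomic_ranks())
    stop("unknown rank: ", rank)
  if (!rank %in% names(taxonomy))
    stop("taxonomy has no '", rank, "' column")
  m <- unclass(table)
  idx <- match(colnames(m), taxonomy$taxon_id)
  lab <- as.character(taxonomy[[rank]][idx])
  lab[is.na(idx) | is.na(lab) | lab == ""] <- "Unclassified"
  if (proteobacteria_to_class && rank == "phylum") {
    is_proteo <- !is.na(idx) & !is.na(taxonomy$phylum[idx]) &
      taxonomy$phylum[idx] == "Proteobacteria"
    cls <- if ("class" %in% names(taxonomy))
      as.character(taxonomy$class[idx]) else rep(NA_character_, length(idx))
    lab[is_proteo] <- ifelse(is.na(cls[is_proteo]) | cls[is_proteo] == "",
                             "Unclassified Proteobacteria", cls[is_proteo])
  }
  agg <- t(rowsum(t(m), group = lab))
  agg <- agg[, order(colnames(agg)), drop = FALSE]
  if (is_count_table(table)) {
    storage.mode(agg) <- "integer"
    structure(agg, class = class(table))
  } else {
    structure(agg, class = class(table))
  }
}
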