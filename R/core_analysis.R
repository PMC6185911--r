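#' Extract the core community of one group
#'
#' The core of a group is the set of taxa with a non-zero count in at least
#' `ceiling(threshold * n)` of the group's samples; at the default
#' `threshold = 1` a taxon must be present in every replicate — the
#' restrictive occurrence rule this package is built around. Taxa observed
#' in the group but failing the rule form the variable community.
#'
#' @param table a [count_table()] (normally already rarefied).
#' @param meta matching `sample_metadata`.
#' @param group group label (a sponge species, or `"seawater"`).
#' @param threshold occurrence fraction in (0, 1].
#' @return object of class `core_set`: list with `group`, `threshold`,
#'   `taxa` (core taxon ids), `variable_taxa`, `n_samples`,
#'   `per_replicate_core_fraction` (share of each replicate's reads on core
#'   taxa), `mean_core_fraction`, `sd_core_fraction`, and `mean_abundance`
#'   (per-core-taxon mean relative abundance across the group's replicates).
#' @export
extract_core <- function(table, meta, group, threshold = 1.0) {
  stopifnot(is_count_table(table))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ids <- intersect(samples_of(meta, group), rownames(table))
  if (!length(ids)) stop("no samples of group '", group, "' in the table")
  if (length(ids) == 1L)
    warning("group '", group, "' has a single sample; its core is just that ",
            "sample's observed taxa")
  m <- ct_matrix(table)[ids, , drop = FALSE]
  n <- length(ids)
  occ <- colSums(m > 0)
  need <- ceiling(threshold * n)
  core <- colnames(m)[occ >= need]
  observed <- colnames(m)[occ > 0]
  rel <- sweep(m, 1L, rowSums(m), "/")
  frac <- if (length(core)) rowSums(rel[, core, drop = FALSE]) else
    stats::setNames(rep(0, n), ids)
  mean_ab <- if (length(core)) colMeans(rel[, core, drop = FALSE]) else
    stats::setNames(numeric(0), character(0))
  structure(list(
    group = group,
    threshold = threshold,
    taxa = core,
    variable_taxa = setdiff(observed, core),
    n_samples = n,
    per_replicate_core_fraction = frac,
    mean_core_fraction = mean(frac),
    sd_core_fraction = if (n > 1L) stats::sd(frac) else 0,
    mean_abundance = mean_ab
  ), class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf(
    "<core_set> group '%s': %d core taxa (threshold %.2f, n = %d), %.1f%% +/- %.1f%% of reads\n",
    x$group, length(x$taxa), x$threshold, x$n_samples,
    100 * x$mean_core_fraction, 100 * x$sd_core_fraction))
  invisible(x)
}

#' Extract cores for every sponge group
#'
#' Convenience wrapper running [extract_core()] for each non-seawater group
#' in the metadata.
#'
#' @inheritParams extract_core
#' @return named list of `core_set` objects.
#' @export
extract_all_cores <- function(table, meta, threshold = 1.0) {
  groups <- unique(meta$group[meta$habitat_class != "SW"])
  stats::setNames(lapply(groups, function(g)
    extract_core(table, meta, g, threshold)), groups)
}

#' Species-specific taxa across a set of cores
#'
#' A taxon is species-specific when it belongs to exactly one core among
#' the cores supplied. Membership is tested against cores only — a
#' species-specific taxon may still occur in other groups' variable
#' communities or in seawater. For each group the summed mean relative
#' abundance of its species-specific taxa is reported as a percentage of
#' that group's core abundance.
#'
#' @param cores named list of `core_set` objects (>= 2).
#' @return data.frame with one row per group: `group`, `n_specific`,
#'   `pct_of_core`; the taxon sets are in `attr(, "taxa")` (named list).
#' @export
species_specific <- function(cores) {
  if (length(cores) < 2L) stop("need at least two cores")
  all_taxa <- unlist(lapply(cores, `[[`, "taxa"), use.names = FALSE)
  counts <- table(all_taxa)
  unique_taxa <- names(counts)[counts == 1L]
  sets <- lapply(cores, function(cs) intersect(cs$taxa, unique_taxa))
  pct <- vapply(seq_along(cores), function(i) {
    cs <- cores[[i]]
    if (!length(sets[[i]]) || !length(cs$taxa)) return(0)
    100 * sum(cs$mean_abundance[sets[[i]]]) / sum(cs$mean_abundance)
  }, numeric(1))
  out <- data.frame(group = names(cores),
                    n_specific = lengths(sets),
                    pct_of_core = pct,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "taxa") <- sets
  out
}

#' Per-species summary of core, species-specific and seawater-shared taxa
#'
#' One row per sponge species with the nine columns of the standard survey
#' summary: replicate count, mean observed richness (after rarefaction),
#' core size, core share of total reads, species-specific counts and their
#' share of the core's abundance, and seawater-core-shared counts and their
#' share of the core's abundance. Percentages for species-specific and
#' seawater-shared taxa use the core community's reads as denominator; the
#' core share itself is relative to each replicate's total reads.
#'
#' @param table rarefied [count_table()].
#' @param meta matching `sample_metadata`.
#' @param cores named list of `core_set` objects (see [extract_all_cores()]).
#' @param overlaps optional named list of `sw_overlap` objects computed
#'   against the seawater core reference ([sw_overlap()]); when absent the
#'   seawater columns are `NA` with a warning.
#' @return data.frame of class `species_summary`.
#' @export
core_summary <- function(table, meta, cores, overlaps = NULL) {
  spsp <- species_specific(cores)
  m <- ct_matrix(table)
  if (is.null(overlaps))
    warning("no seawater overlap reports supplied; SW columns set to NA")
  rows <- lapply(names(cores), function(g) {
    cs <- cores[[g]]
    ids <- intersect(samples_of(meta, g), rownames(table))
    rich <- rowSums(m[ids, , drop = FALSE] > 0)
    i <- match(g, spsp$group)
    ov <- if (!is.null(overlaps)) overlaps[[g]] else NULL
    data.frame(
      group = g,
      n_replicates = cs$n_samples,
      mean_richness = mean(rich),
      sd_richness = if (length(rich) > 1L) stats::sd(rich) else 0,
      core_size = length(cs$taxa),
      core_fraction_pct = 100 * cs$mean_core_fraction,
      core_fraction_sd = 100 * cs$sd_core_fraction,
      n_species_specific = spsp$n_specific[i],
      species_specific_pct_of_core = spsp$pct_of_core[i],
      n_sw_shared = if (is.null(ov)) NA_integer_ else length(ov$shared_taxa),
      sw_shared_pct_of_core = if (is.null(ov)) NA_real_ else ov$pct_of_sponge_core,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Rank correlation of core size and core abundance with replicate number
#'
#' Spearman correlations of (i) replicate count vs core size — expected
#' negative, since with more replicates the all-replicate occurrence rule is
#' harder to satisfy — and (ii) replicate count vs the core's share of
#' reads, which should not depend on sampling effort.
#'
#' @param summaries a `species_summary` data.frame (or any data.frame with
#'   columns `n_replicates`, `core_size`, `core_fraction_pct`), >= 4 rows.
#' @return list with elements `size` and `abundance`, each a [spearman()]
#'   result (`rho`, `p`).
#' @export
core_size_vs_replicates <- function(summaries) {
  if (nrow(summaries) < 4L) stop("need at least 4 species")
  list(size = spearman(summaries$n_replicates, summaries$core_size),
       abundance = spearman(summaries$n_replicates, summaries$core_fraction_pct))
}
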