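#' Seawater core reference (cosmopolitan bacteria)
#'
#' Taxa present in all seawater replicates — the same all-replicate
#' occurrence rule used for sponge cores, applied to the water samples.
#' These are the bacteria consistently available in the water column, rare
#' or abundant, and therefore a plausible seed bank for sponge microbiomes.
#'
#' @param table a [count_table()] (normally rarefied).
#' @param meta matching `sample_metadata`; needs >= 2 SW samples.
#' @return object of class `sw_reference` with `method = "core"`, the taxon
#'   set, and `sw_mean_abundance`: mean relative abundance of every taxon
#'   across all water samples (proportions).
#' @export
sw_core <- function(table, meta) {
  ws <- intersect(water_samples(meta), rownames(table))
  if (!length(ws)) stop("no seawater samples")
  if (length(ws) < 2L) warning("single seawater sample; core = its observed taxa")
  cs <- extract_core(table, meta, "seawater", threshold = 1.0)
  m <- ct_matrix(table)[ws, , drop = FALSE]
  rel <- sweep(m, 1L, rowSums(m), "/")
  structure(list(method = "core", taxa = cs$taxa,
                 sw_mean_abundance = colMeans(rel),
                 n_sw_samples = length(ws)),
            class = "sw_reference")
}

#' Abundant seawater reference
#'
#' Taxa whose mean relative abundance across all water samples is strictly
#' greater than `cutoff` percent (default 0.01%, the threshold commonly
#' used to flag likely environmental contaminants in sponge samples).
#'
#' @param table a [count_table()].
#' @param meta matching `sample_metadata`; needs >= 1 SW sample.
#' @param cutoff mean relative abundance cutoff, in percent (strict `>`).
#' @return object of class `sw_reference` with `method = "abundant"`.
#' @export
abundant_sw <- function(table, meta, cutoff = 0.01) {
  ws <- intersect(water_samples(meta), rownames(table))
  if (!length(ws)) stop("no seawater samples")
  m <- ct_matrix(table)[ws, , drop = FALSE]
  rel <- sweep(m, 1L, rowSums(m), "/")
  mean_ab <- colMeans(rel)
  taxa <- names(mean_ab)[100 * mean_ab > cutoff]
  structure(list(method = "abundant", taxa = taxa,
                 sw_mean_abundance = mean_ab, cutoff = cutoff,
                 n_sw_samples = length(ws)),
            class = "sw_reference")
}

#' @export
print.sw_reference <- function(x, ...) {
  cat(sprintf("<sw_reference> method '%s': %d taxa over %d seawater samples\n",
              x$method, length(x$taxa), x$n_sw_samples))
  invisible(x)
}

#' Overlap between one sponge core and a seawater reference
#'
#' Quantifies how much of a sponge species' core community is made of
#' seawater bacteria. `pct_of_sponge_core` is the summed mean relative
#' abundance of the shared taxa within the species' replicates, expressed
#' as a percentage of the core community's abundance (not of the whole
#' microbiome). `pct_of_sw_reference` is the analogous share of the shared
#' taxa within the water samples, relative to the reference's summed
#' abundance — so a species can hold e.g. 90% of its core in taxa that make
#' up only 5% of the seawater core, the signature of enrichment of rare
#' seawater bacteria. Means are taken per taxon first and then summed, so
#' both percentages decompose per taxon.
#'
#' @param core a `core_set` ([extract_core()]); must be non-empty.
#' @param ref an `sw_reference` ([sw_core()] / [abundant_sw()]) from the
#'   same rarefied table.
#' @return object of class `sw_overlap`: `group`, `method`, `shared_taxa`,
#'   `pct_of_sponge_core`, `pct_of_sw_reference`, and `per_taxon` — a
#'   data.frame with each shared taxon's mean relative abundance in the
#'   sponge replicates (`sponge_ra`), its share of the core
#'   (`pct_of_core`), its mean seawater abundance in percent (`sw_pct`),
#'   rarity class and enrichment ratio (sponge over seawater abundance).
#' @export
sw_overlap <- function(core, ref) {
  if (!inherits(core, "core_set")) stop("`core` must be a core_set")
  if (!inherits(ref, "sw_reference")) stop("`ref` must be an sw_reference")
  if (!length(core$taxa)) stop("empty sponge core for group '", core$group, "'")
  shared <- intersect(core$taxa, ref$taxa)
  core_total <- sum(core$mean_abundance)
  ref_total <- sum(ref$sw_mean_abundance[ref$taxa])
  sponge_ra <- core$mean_abundance[shared]
  sw_ra <- ref$sw_mean_abundance[shared]
  per_taxon <- data.frame(
    taxon = shared,
    sponge_ra = unname(sponge_ra),
    pct_of_core = if (core_total > 0) 100 * unname(sponge_ra) / core_total else 0,
    sw_pct = 100 * unname(sw_ra),
    rarity = rarity_class(100 * unname(sw_ra)),
    enrichment_ratio = unname(ifelse(sw_ra > 0, sponge_ra / sw_ra, Inf)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    group = core$group, method = ref$method, shared_taxa = shared,
    pct_of_sponge_core = if (core_total > 0) 100 * sum(sponge_ra) / core_total else 0,
    pct_of_sw_reference = if (ref_total > 0) 100 * sum(sw_ra) / ref_total else 0,
    per_taxon = per_taxon), class = "sw_overlap")
}

#' @export
print.sw_overlap <- function(x, ...) {
  cat(sprintf(
    "<sw_overlap> '%s' vs SW %s reference: %d shared taxa; %.1f%% of sponge core, %.1f%% of SW reference\n",
    x$group, x$method, length(x$shared_taxa),
    x$pct_of_sponge_core, x$pct_of_sw_reference))
  invisible(x)
}

#' Overlap of every sponge core against a seawater reference
#' @param cores named list of `core_set` objects.
#' @param ref an `sw_reference`.
#' @return named list of `sw_overlap` objects.
#' @export
sw_overlap_all <- function(cores, ref) {
  stats::setNames(lapply(cores, sw_overlap, ref = ref), names(cores))
}

#' Classify taxa by seawater abundance
#'
#' Rare below 0.01%, highly abundant above 1%, intermediate otherwise
#' (boundaries exclusive on both sides).
#'
#' @param sw_abundance mean relative abundance(s) in percent; must be >= 0.
#' @return character vector: `"rare"`, `"intermediate"` or `"abundant"`.
#' @export
rarity_class <- function(sw_abundance) {
  if (any(sw_abundance < 0)) stop("abundance must be non-negative")
  ifelse(sw_abundance < 0.01, "rare",
         ifelse(sw_abundance > 1, "abundant", "intermediate"))
}

#' Difference in seawater overlap between the two reference methods
#'
#' `pct_of_sponge_core` against the seawater core minus the same quantity
#' against the abundant-seawater reference. Large positive values flag
#' species whose core relies on seawater bacteria that are cosmopolitan but
#' rare in the water — taxa the abundant-seawater reference misses.
#'
#' @param report_core `sw_overlap` computed against [sw_core()].
#' @param report_abundant `sw_overlap` for the same group against
#'   [abundant_sw()].
#' @return signed difference in percentage points.
#' @export
method_difference <- function(report_core, report_abundant) {
  if (report_core$group != report_abundant$group)
    stop("reports belong to different groups ('", report_core$group, "' vs '",
         report_abundant$group, "')")
  report_core$pct_of_sponge_core - report_abundant$pct_of_sponge_core
}

#' Flag species enriching rare seawater bacteria
#'
#' For each species, the score is the share of its core community's
#' abundance (in percent of core) carried by seawater-core taxa that are
#' rare in the water (mean seawater abundance below `rare_cutoff` percent).
#' A species is flagged when the score exceeds `dominance_cutoff`: its
#' microbiome is dominated by bacteria it must have concentrated far above
#' their seawater availability. The default cutoff of 50 ("more than half
#' of the core") is a package choice, documented rather than prescribed.
#'
#' @param reports named list of `sw_overlap` objects computed against the
#'   seawater core reference.
#' @param rare_cutoff seawater abundance below which a taxon counts as
#'   rare, percent.
#' @param dominance_cutoff score above which a species is flagged, percent
#'   of core abundance.
#' @return data.frame: `group`, `score`, `flag`.
#' @export
enrichment_flags <- function(reports, rare_cutoff = 0.01, dominance_cutoff = 50) {
  if (any(vapply(reports, `[[`, "", "method") != "core"))
    stop("enrichment flags are defined for seawater-core overlap reports")
  score <- vapply(reports, function(r) {
    pt <- r$per_taxon
    sum(pt$pct_of_core[pt$sw_pct < rare_cutoff])
  }, numeric(1))
  data.frame(group = names(reports), score = unname(score),
             flag = unname(score > dominance_cutoff),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' List possible seawater-contamination cases
#'
#' Conservative reporting rule: a seawater taxon that is highly abundant in
#' the water (above `sw_abundant_cutoff` percent) but present in a sponge
#' core at trace level (below `sponge_rare_cutoff` percent of the core's
#' abundance) may simply reflect carry-over of water through the sponge,
#' especially for species with few replicates. Such cases are listed for
#' inspection, never removed automatically.
#'
#' @param reports named list of `sw_overlap` objects (seawater-core method).
#' @param sw_abundant_cutoff percent; seawater abundance above this flags
#'   the taxon as highly abundant.
#' @param sponge_rare_cutoff percent of core abundance below which the
#'   sponge-side presence counts as trace.
#' @return data.frame: `group`, `taxon`, `sw_pct`, `pct_of_core`.
#' @export
potential_contamination <- function(reports, sw_abundant_cutoff = 1,
                                    sponge_rare_cutoff = 0.01) {
  rows <- lapply(reports, function(r) {
    pt <- r$per_taxon
    hit <- pt$sw_pct > sw_abundant_cutoff & pt$pct_of_core < sponge_rare_cutoff
    if (!any(hit)) return(NULL)
    data.frame(group = r$group, taxon = pt$taxon[hit], sw_pct = pt$sw_pct[hit],
               pct_of_core = pt$pct_of_core[hit],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), taxon = character(),
                      sw_pct = numeric(), pct_of_core = numeric())
  rownames(out) <- NULL
  out
}
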