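#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over the non-zero proportions of the vector. Nats,
#' since field-standard HMA/LMA sponge core diversities (around 3.8 vs 2.3)
#' are on the natural-log scale.
#'
#' @param counts non-negative vector of counts or abundances with at least
#'   one positive entry.
#' @return H in nats.
#' @export
shannon <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero vector")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(u, v) = sum |u_i - v_i| / sum (u_i + v_i), computed between all sample
#' pairs (via [vegan::vegdist()]). On relative abundances this is invariant
#' to per-sample sequencing depth.
#'
#' @param table samples x taxa matrix ([count_table()] or
#'   `abundance_table`); >= 2 samples, no all-zero sample.
#' @return a `dist` object with entries in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("need at least 2 samples")
  if (any(rowSums(m) == 0)) stop("all-zero sample(s): distance undefined")
  vegan::vegdist(m, method = "bray")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties get average ranks),
#' with the p-value from the t approximation — the standard large-sample
#' treatment.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rho` and `p`; if either vector is constant the
#'   correlation is undefined and both are `NA` with `defined = FALSE`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic with tie correction and a chi-square p-value on g - 1
#' degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param groups list of >= 2 numeric vectors, each non-empty.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Wrapper around [stats::hclust()] with the labels put in lexicographic
#' order first, so equal-distance merges resolve the same way regardless of
#' input ordering.
#'
#' @param D a `dist` object (e.g. from [bray_curtis()]), n >= 2.
#' @param linkage `"average"` (UPGMA, default), `"complete"` or `"single"`.
#' @return an `hclust` tree.
#' @export
hcluster <- function(D, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(D)
  if (nrow(m) < 2L) stop("need at least 2 observations")
  ord <- order(rownames(m))
  stats::hclust(stats::as.dist(m[ord, ord]), method = linkage)
}

#' Export a dendrogram in Newick format
#'
#' @param tree an `hclust` object.
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Heatmap export of seawater-core taxa across sponge cores
#'
#' Builds the species x taxon matrix of shared seawater-core taxon
#' abundances (percent of each species' core), keeps the taxa reaching more
#' than `abundance_floor` percent in at least one sponge core, and attaches
#' average-linkage Bray-Curtis dendrograms for both axes — the data behind
#' the classic "cosmopolitan seawater bacteria across sponge species"
#' heatmap. Species-mean profiles (not replicate-level) are clustered.
#'
#' @param reports named list of `sw_overlap` objects computed against the
#'   seawater core reference.
#' @param abundance_floor percent of core abundance a taxon must exceed in
#'   at least one species to be retained (default 1).
#' @param taxonomy optional [taxonomy_table()] used to attach a taxon label
#'   (phylum, class for Proteobacteria) to the long-format table.
#' @return list with `long` (group, taxon, pct_of_core, label), `matrix`
#'   (species x taxa), `species_tree`, `taxon_tree` (hclust or `NULL` when
#'   an axis has < 2 entries), `species_order`, `taxon_order`.
#' @export
heatmap_export <- function(reports, abundance_floor = 1.0, taxonomy = NULL) {
  groups <- names(reports)
  taxa <- sort(unique(unlist(lapply(reports, function(r) r$per_taxon$taxon))))
  M <- matrix(0, nrow = length(groups), ncol = length(taxa),
              dimnames = list(groups, taxa))
  for (g in groups) {
    pt <- reports[[g]]$per_taxon
    if (nrow(pt)) M[g, pt$taxon] <- pt$pct_of_core
  }
  keep <- colnames(M)[apply(M, 2L, max) > abundance_floor]
  if (!length(keep)) {
    warning("no taxon exceeds the abundance floor; empty export")
    return(list(long = data.frame(group = character(), taxon = character(),
                                  pct_of_core = numeric(), label = character()),
                matrix = M[, 0, drop = FALSE],
                species_tree = NULL, taxon_tree = NULL,
                species_order = character(), taxon_order = character()))
  }
  Mk <- M[, keep, drop = FALSE]
  sp_tree <- tx_tree <- NULL
  sp_order <- rownames(Mk)
  tx_order <- colnames(Mk)
  nonzero_rows <- rowSums(Mk) > 0
  if (sum(nonzero_rows) >= 2L) {
    sp_tree <- hcluster(bray_curtis(Mk[nonzero_rows, , drop = FALSE]))
    sp_order <- c(sp_tree$labels[sp_tree$order],
                  rownames(Mk)[!nonzero_rows])
  }
  if (ncol(Mk) >= 2L) {
    tx_tree <- hcluster(bray_curtis(t(Mk)))
    tx_order <- tx_tree$labels[tx_tree$order]
  }
  long <- data.frame(
    group = rep(rownames(Mk), times = ncol(Mk)),
    taxon = rep(colnames(Mk), each = nrow(Mk)),
    pct_of_core = as.vector(Mk),
    stringsAsFactors = FALSE)
  long$label <- if (!is.null(taxonomy)) {
    idx <- match(long$taxon, taxonomy$taxon_id)
    lab <- as.character(taxonomy$phylum[idx])
    if ("class" %in% names(taxonomy)) {
      pro <- !is.na(lab) & lab == "Proteobacteria" &
        !is.na(taxonomy$class[idx])
      lab[pro] <- as.character(taxonomy$class[idx][pro])
    }
    lab[is.na(lab)] <- "Unclassified"
    lab
  } else NA_character_
  list(long = long, matrix = Mk, species_tree = sp_tree, taxon_tree = tx_tree,
       species_order = sp_order, taxon_order = tx_order)
}
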