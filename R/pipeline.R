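#' Default run configuration
#'
#' Aggregates every numeric setting of the standard analysis: rarefaction
#' depth 41000, all-replicate occurrence rule, abundant-seawater cutoff
#' 0.01%, rare/abundant rarity cutoffs 0.01%/1%, heatmap floor 1%, 999
#' permutations, alpha 0.05 (0.01 for IndVal with threshold 0.6). Values
#' can be overridden by name.
#'
#' @param ... overrides, e.g. `depth = 20000`, `output_dir = "out"`.
#' @return list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    count_table = NULL, metadata = NULL, taxonomy = NULL,
    format = "tsv", samples_as_rows = FALSE, permissive = FALSE,
    depth = 41000, rarefy_seed = 1,
    occurrence_threshold = 1.0,
    sw_abundance_cutoff = 0.01,
    rare_cutoff = 0.01, abundant_cutoff = 1,
    heatmap_floor = 1,
    n_perm = 999, perm_seed = 1,
    alpha = 0.05, indval_threshold = 0.6, indval_alpha = 0.01,
    dominance_cutoff = 50,
    output_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$occurrence_threshold > 0, cfg$occurrence_threshold <= 1,
            cfg$depth >= 1, cfg$n_perm >= 1,
            cfg$sw_abundance_cutoff >= 0, cfg$heatmap_floor >= 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Any field of [default_run_config()] may appear; missing fields keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_run_config, vals)
}

write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis end to end
#'
#' Executes rarefaction, per-species core extraction, species-specific
#' identification, both seawater references, both overlap quantifications,
#' the survey-style per-species summary, core-community Shannon diversity
#' with the HMA/LMA rank test, PERMANOVA and PERMDISP for the host-species
#' and HMA/LMA factors, phylum/class IndVal for HMA vs LMA, and the
#' seawater-core heatmap export. When `config$output_dir` is set, all
#' tabular results are written as TSV, trees as Newick, and a manifest
#' (parameters, seeds, group sizes, dropped samples) as YAML; reruns with
#' the same config and inputs are byte-identical.
#'
#' @param config a `run_config` ([default_run_config()] /
#'   [read_run_config()]). Inputs are taken from the `count_table`,
#'   `metadata`, `taxonomy` path fields, or passed directly via `counts`,
#'   `meta`, `taxonomy` arguments.
#' @param counts optional in-memory [count_table()] (overrides the path).
#' @param meta optional in-memory `sample_metadata`.
#' @param taxonomy optional in-memory `taxonomy_table`.
#' @return (invisibly) a list with every intermediate and final result.
#' @export
run_all <- function(config = default_run_config(), counts = NULL, meta = NULL,
                    taxonomy = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(counts))
    counts <- stage("read_counts", read_count_table(
      config$count_table, config$format, config$samples_as_rows))
  if (is.null(meta))
    meta <- stage("read_metadata", read_metadata(config$metadata))
  if (is.null(taxonomy) && !is.null(config$taxonomy))
    taxonomy <- stage("read_taxonomy", read_taxonomy(config$taxonomy))
  pair <- stage("validate", validate_pair(counts, meta, config$permissive))
  counts <- pair$table; meta <- pair$meta

  rare <- stage("rarefy", rarefy(counts, config$depth, config$rarefy_seed))
  meta <- meta[meta$sample_id %in% rownames(rare), , drop = FALSE]
  rel <- to_relative_abundance(rare)

  cores <- stage("core", extract_all_cores(rare, meta, config$occurrence_threshold))
  spsp <- stage("species_specific", species_specific(cores))
  ref_core <- stage("sw_core", sw_core(rare, meta))
  ref_abund <- stage("abundant_sw",
                     abundant_sw(rare, meta, config$sw_abundance_cutoff))
  ov_core <- stage("overlap_core", sw_overlap_all(cores, ref_core))
  ov_abund <- stage("overlap_abundant", sw_overlap_all(cores, ref_abund))
  summary_tab <- stage("summary", core_summary(rare, meta, cores, ov_core))
  corr <- stage("correlations", core_size_vs_replicates(summary_tab))
  mdiff <- vapply(names(cores), function(g)
    method_difference(ov_core[[g]], ov_abund[[g]]), numeric(1))
  flags <- enrichment_flags(ov_core, config$rare_cutoff, config$dominance_cutoff)
  contam <- potential_contamination(ov_core, config$abundant_cutoff,
                                    config$rare_cutoff)

  ## core-community Shannon per replicate, averaged per species
  shan <- stage("shannon", {
    m <- ct_matrix(rare)
    rows <- lapply(names(cores), function(g) {
      cs <- cores[[g]]
      ids <- intersect(samples_of(meta, g), rownames(rare))
      h <- vapply(ids, function(s) shannon(m[s, cs$taxa]), numeric(1))
      data.frame(group = g,
                 habitat_class = meta$habitat_class[match(g, meta$group)],
                 mean_shannon = mean(h),
                 sd_shannon = if (length(h) > 1) stats::sd(h) else 0,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  kw <- kruskal_wallis(split(shan$mean_shannon, shan$habitat_class))

  sponge_ids <- meta$sample_id[meta$habitat_class != "SW"]
  rel_sponge <- unclass(rel)[sponge_ids, , drop = FALSE]
  D_all <- bray_curtis(rel)
  D_sponge <- stats::as.dist(as.matrix(D_all)[sponge_ids, sponge_ids])
  lab_species <- stats::setNames(meta$group, meta$sample_id)[sponge_ids]
  lab_habitat <- stats::setNames(meta$habitat_class, meta$sample_id)[sponge_ids]

  perma_species <- stage("permanova_species",
    permanova(D_sponge, lab_species, config$n_perm, config$perm_seed))
  perma_habitat <- stage("permanova_habitat",
    permanova(D_sponge, lab_habitat, config$n_perm, config$perm_seed))
  disp_species <- stage("permdisp_species",
    permdisp(D_sponge, lab_species, TRUE, config$n_perm, config$perm_seed))
  disp_habitat <- stage("permdisp_habitat",
    permdisp(D_sponge, lab_habitat, TRUE, config$n_perm, config$perm_seed))

  iv <- NULL
  if (!is.null(taxonomy)) {
    agg <- aggregate_taxa(rel, taxonomy, "phylum", proteobacteria_to_class = TRUE)
    iv <- stage("indval", indval(agg[sponge_ids, , drop = FALSE], lab_habitat,
                                 config$indval_threshold, config$indval_alpha,
                                 config$n_perm, config$perm_seed))
  }
  hm <- stage("heatmap", heatmap_export(ov_core, config$heatmap_floor, taxonomy))
  dendro <- hcluster(D_all)

  out <- list(rarefied = rare, relative = rel, meta = meta, cores = cores,
              species_specific = spsp, sw_core_ref = ref_core,
              sw_abundant_ref = ref_abund, overlap_core = ov_core,
              overlap_abundant = ov_abund, summary = summary_tab,
              correlations = corr, method_difference = mdiff,
              enrichment = flags, contamination = contam,
              shannon = shan, kruskal_habitat = kw,
              permanova_species = perma_species,
              permanova_habitat = perma_habitat,
              permdisp_species = disp_species,
              permdisp_habitat = disp_habitat,
              indval = iv, heatmap = hm, sample_dendrogram = dendro,
              config = config)

  dir <- config$output_dir
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(summary_tab, dir, "species_summary.tsv")
    write_tsv(spsp, dir, "species_specific.tsv")
    core_long <- do.call(rbind, lapply(cores, function(cs)
      data.frame(group = cs$group, taxon = cs$taxa, stringsAsFactors = FALSE)))
    write_tsv(core_long, dir, "core_taxa.tsv")
    ov_rows <- function(ovs) do.call(rbind, lapply(ovs, function(o)
      data.frame(group = o$group, method = o$method,
                 n_shared = length(o$shared_taxa),
                 pct_of_sponge_core = o$pct_of_sponge_core,
                 pct_of_sw_reference = o$pct_of_sw_reference,
                 stringsAsFactors = FALSE)))
    write_tsv(rbind(ov_rows(ov_core), ov_rows(ov_abund)), dir, "sw_overlap.tsv")
    per_taxon <- do.call(rbind, lapply(ov_core, function(o)
      cbind(group = o$group, o$per_taxon)))
    write_tsv(per_taxon, dir, "sw_overlap_per_taxon.tsv")
    write_tsv(data.frame(group = names(mdiff), difference = unname(mdiff)),
              dir, "method_difference.tsv")
    write_tsv(flags, dir, "enrichment_flags.tsv")
    write_tsv(contam, dir, "potential_contamination.tsv")
    write_tsv(shan, dir, "core_shannon.tsv")
    stats_tab <- data.frame(
      test = c("permanova_species", "permanova_hma_lma",
               "permdisp_species", "permdisp_hma_lma", "kruskal_shannon"),
      statistic = c(perma_species$pseudo_F, perma_habitat$pseudo_F,
                    disp_species$F, disp_habitat$F, kw$H),
      R2 = c(perma_species$R2, perma_habitat$R2, NA, NA, NA),
      p = c(perma_species$p_perm, perma_habitat$p_perm,
            disp_species$p_perm, disp_habitat$p_perm, kw$p))
    write_tsv(stats_tab, dir, "multivariate_stats.tsv")
    if (!is.null(iv)) write_tsv(iv, dir, "indval.tsv")
    write_tsv(hm$long, dir, "heatmap_long.tsv")
    if (!is.null(hm$species_tree))
      dendrogram_newick(hm$species_tree, file.path(dir, "heatmap_species.nwk"))
    if (!is.null(hm$taxon_tree))
      dendrogram_newick(hm$taxon_tree, file.path(dir, "heatmap_taxa.nwk"))
    dendrogram_newick(dendro, file.path(dir, "sample_dendrogram.nwk"))
    pars <- unclass(config)
    pars$output_dir <- NULL  # derivable from the manifest's own location
    manifest <- list(
      package_version = as.character(utils::packageVersion("spongecore")),
      parameters = pars[!vapply(pars, is.null, TRUE)],
      dropped_samples = as.character(attr(rare, "dropped")),
      n_samples = nrow(rare), n_taxa = ncol(rare),
      groups = as.list(table(meta$group)))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  }
  invisible(out)
}
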