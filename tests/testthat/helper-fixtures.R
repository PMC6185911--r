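# Fixtures and independent brute-force oracles shared across the suite.

toy_counts <- function(m, samples = NULL, taxa = NULL) {
  if (!is.null(samples)) rownames(m) <- samples
  if (!is.null(taxa)) colnames(m) <- taxa
  count_table(m)
}

# 3 sponge species x 3 replicates + 3 seawater samples over 8 taxa,
# hand-set counts used by several set-algebra tests
toy_dataset <- function() {
  taxa <- paste0("t", 1:8)
  counts <- rbind(
    A_1 = c(50, 30, 10,  5, 0, 0, 3, 2),
    A_2 = c(45, 35, 12,  0, 0, 0, 4, 4),
    A_3 = c(55, 25,  8,  7, 0, 0, 2, 3),
    B_1 = c(40,  0, 30, 20, 5, 0, 3, 2),
    B_2 = c(35,  0, 28, 25, 7, 0, 5, 0),
    B_3 = c(42,  0, 33, 18, 6, 0, 2, 1),
    C_1 = c( 0, 20,  0,  0, 0, 60, 10, 10),
    C_2 = c( 0, 25,  0,  0, 0, 55, 12,  8),
    C_3 = c( 0, 22,  0,  0, 0, 58,  9, 11),
    SW_1 = c(80, 10, 5, 0, 1, 0, 3, 1),
    SW_2 = c(78, 12, 6, 0, 2, 0, 1, 1),
    SW_3 = c(82,  9, 4, 0, 1, 0, 2, 2))
  colnames(counts) <- taxa
  meta <- sample_metadata(data.frame(
    sample_id = rownames(counts),
    group = rep(c("A", "B", "C", "seawater"), each = 3),
    habitat_class = rep(c("HMA", "LMA", "LMA", "SW"), each = 3),
    stringsAsFactors = FALSE))
  list(counts = count_table(counts), meta = meta)
}

small_template <- function() {
  data.frame(
    species = c("sp1", "sp2", "sp3", "sp4"),
    hma = c(1, 0, 0, 0),
    n = c(4, 3, 2, 3),
    mean_zotus = c(100, 120, 90, 110), sd_zotus = c(10, 10, 10, 10),
    core_zotus = c(30, 25, 20, 28),
    core_pct = c(85, 80, 75, 82), core_pct_sd = c(3, 3, 3, 3),
    spsp_zotus = c(4, 3, 0, 5),
    spsp_pct = c(5, 3, 0, 6),
    sw_zotus = c(10, 8, 12, 6),
    sw_pct = c(40, 55, 70, 20),
    stringsAsFactors = FALSE)
}

small_params <- function(...) {
  args <- list(template = small_template(), n_sw_samples = 5,
               regional_pool_size = 400, sw_core_abundant_size = 30,
               sw_core_rare_size = 15, depth = 5000,
               rare_core_species = "sp3")
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

# the full default synthetic dataset at the pinned seed, built once per run
default_sim_env <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(default_sim_env$sim)) {
    sim <- simulate_communities(sim_params(), seed = 101)
    cores <- extract_all_cores(sim$counts, sim$metadata)
    spsp <- species_specific(cores)
    ref_core <- sw_core(sim$counts, sim$metadata)
    ref_abund <- abundant_sw(sim$counts, sim$metadata)
    default_sim_env$sim <- list(
      sim = sim, cores = cores, spsp = spsp,
      ref_core = ref_core, ref_abund = ref_abund,
      ov_core = sw_overlap_all(cores, ref_core),
      ov_abund = sw_overlap_all(cores, ref_abund))
  }
  default_sim_env$sim
}

# hand-set 4-sample distance matrix for sum-of-squares oracles
four_point_D <- function() {
  m <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  m["s1", "s2"] <- m["s2", "s1"] <- 0.2
  m["s1", "s3"] <- m["s3", "s1"] <- 0.8
  m["s1", "s4"] <- m["s4", "s1"] <- 0.9
  m["s2", "s3"] <- m["s3", "s2"] <- 0.7
  m["s2", "s4"] <- m["s4", "s2"] <- 0.85
  m["s3", "s4"] <- m["s4", "s3"] <- 0.3
  stats::as.dist(m)
}

## ---- independent oracles -------------------------------------------------

# average ranks by direct counting (no rank())
rank_avg <- function(v) {
  vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
}

bf_spearman_rho <- function(x, y) {
  rx <- rank_avg(x); ry <- rank_avg(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# naive UPGMA agglomeration: merge height = mean original inter-cluster
# distance; returns sorted merge heights
bf_upgma_heights <- function(D) {
  m <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- mean(m[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(j, i) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# exhaustive Dufrene-Legendre A x B per taxon and group
bf_indval <- function(m, groups) {
  g <- unique(groups)
  out <- matrix(0, length(g), ncol(m), dimnames = list(g, colnames(m)))
  for (gg in g) {
    idx <- which(groups == gg)
    for (t in seq_len(ncol(m))) {
      means <- vapply(g, function(h) mean(m[groups == h, t]), numeric(1))
      A <- if (sum(means) > 0) means[[gg]] / sum(means) else 0
      B <- mean(m[idx, t] > 0)
      out[gg, t] <- A * B
    }
  }
  out
}

# direct evaluation of the PERMANOVA sums of squares on a distance matrix
bf_permanova <- function(D, groups) {
  m <- as.matrix(D)^2
  N <- nrow(m)
  ss_tot <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) if (i < j) ss_tot <- ss_tot + m[i, j]
  ss_tot <- ss_tot / N
  ss_w <- 0
  for (gg in unique(groups)) {
    idx <- which(groups == gg)
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + m[i, j]
    ss_w <- ss_w + acc / length(idx)
  }
  a <- length(unique(groups))
  list(R2 = (ss_tot - ss_w) / ss_tot,
       F = ((ss_tot - ss_w) / (a - 1)) / (ss_w / (N - a)))
}
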