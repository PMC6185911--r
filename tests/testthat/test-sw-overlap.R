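sw_toy <- function(counts) {
  meta <- sample_metadata(data.frame(
    sample_id = rownames(counts), group = "seawater", habitat_class = "SW"))
  list(tab = count_table(counts), meta = meta)
}

test_that("the seawater core applies the all-replicate rule over water samples", {
  # t1 present in all 9 water replicates, t2 in 8 of 9
  m <- matrix(5L, nrow = 9, ncol = 3,
              dimnames = list(paste0("w", 1:9), c("t1", "t2", "t3")))
  m[4, "t2"] <- 0L
  m[, "t3"] <- rep(c(1L, 0L, 2L), each = 3)
  w <- sw_toy(m)
  ref <- sw_core(w$tab, w$meta)
  expect_identical(ref$taxa, "t1")
  expect_true(all(ref$taxa %in% colnames(m)[colSums(m) > 0]))
})

test_that("a planted set of shared water taxa is recovered exactly", {
  set.seed(3)
  m <- matrix(rpois(3 * 14, 2), nrow = 3,
              dimnames = list(paste0("w", 1:3), paste0("t", 1:14)))
  m[, 1:10] <- m[, 1:10] + 1L   # ten taxa guaranteed in every sample
  m[1, 11:14] <- 0L             # the rest miss at least the first sample
  w <- sw_toy(m)
  expect_setequal(sw_core(w$tab, w$meta)$taxa, paste0("t", 1:10))
})

test_that("abundant seawater reference uses a strict mean-abundance cutoff", {
  m <- rbind(w1 = c(1L, 2L, 9996L, 1L), w2 = c(1L, 1L, 9997L, 1L),
             w3 = c(1L, 1L, 9997L, 1L))
  colnames(m) <- c("exact", "above", "big", "exact2")
  m[2, "exact2"] <- 0L; m[2, "big"] <- m[2, "big"] + 1L
  m[3, "exact2"] <- 2L; m[3, "big"] <- m[3, "big"] - 1L
  # means: exact = 0.01% sharp, above = 0.0133%, exact2 = 0.01% sharp
  w <- sw_toy(m)
  ref <- abundant_sw(w$tab, w$meta, cutoff = 0.01)
  expect_setequal(ref$taxa, c("above", "big"))
  expect_setequal(abundant_sw(w$tab, w$meta, cutoff = 0)$taxa, colnames(m))
  # reference shrinks monotonically with the cutoff
  sizes <- vapply(c(0, 0.005, 0.01, 0.02, 2), function(cu)
    length(abundant_sw(w$tab, w$meta, cu)$taxa), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("overlap percentages hit their boundary cases and invariances", {
  toy <- toy_dataset()
  cores <- extract_all_cores(toy$counts, toy$meta)
  ref <- sw_core(toy$counts, toy$meta)

  ov <- sw_overlap(cores$A, ref)
  expect_true(all(ov$shared_taxa %in% intersect(cores$A$taxa, ref$taxa)))
  expect_true(ov$pct_of_sponge_core >= 0 && ov$pct_of_sponge_core <= 100)

  # core fully inside the reference and vice versa
  ident <- ref; ident$taxa <- cores$A$taxa
  expect_equal(sw_overlap(cores$A, ident)$pct_of_sponge_core, 100)
  # disjoint reference
  disj <- ref; disj$taxa <- "t6"
  expect_equal(sw_overlap(cores$A, disj)$pct_of_sponge_core, 0)
  expect_equal(sw_overlap(cores$A, disj)$pct_of_sw_reference, 0)

  # invariance to taxon relabelling and sample order
  perm_counts <- unclass(toy$counts)[sample(nrow(toy$counts)), ]
  relab <- setNames(paste0("x", 1:8), paste0("t", 1:8))
  colnames(perm_counts) <- relab[colnames(perm_counts)]
  tab2 <- count_table(perm_counts)
  cores2 <- extract_all_cores(tab2, toy$meta)
  ov2 <- sw_overlap(cores2$A, sw_core(tab2, toy$meta))
  expect_equal(ov2$pct_of_sponge_core, ov$pct_of_sponge_core, tolerance = 1e-12)
  expect_equal(ov2$pct_of_sw_reference, ov$pct_of_sw_reference, tolerance = 1e-12)

  # a bigger reference can only increase the sponge-side overlap
  ov_all <- sw_overlap(cores$A, abundant_sw(toy$counts, toy$meta, cutoff = 0))
  ov_cut <- sw_overlap(cores$A, abundant_sw(toy$counts, toy$meta, cutoff = 1))
  expect_gte(ov_all$pct_of_sponge_core, ov_cut$pct_of_sponge_core)
})

test_that("rarity classes follow the 0.01% and 1% boundaries", {
  expect_identical(rarity_class(c(0.005, 0.5, 2.0)),
                   c("rare", "intermediate", "abundant"))
  expect_identical(rarity_class(c(0.01, 1)),
                   c("intermediate", "intermediate"))  # boundaries exclusive
  expect_error(rarity_class(-0.1), "non-negative")
})

test_that("method difference is zero for identical references and guards groups", {
  toy <- toy_dataset()
  cores <- extract_all_cores(toy$counts, toy$meta)
  ref <- sw_core(toy$counts, toy$meta)
  ov <- sw_overlap(cores$A, ref)
  expect_equal(method_difference(ov, ov), 0)
  ovB <- sw_overlap(cores$B, ref)
  expect_error(method_difference(ov, ovB), "different groups")
})

test_that("enrichment flags score the rare-seawater share of each core", {
  toy <- toy_dataset()
  cores <- extract_all_cores(toy$counts, toy$meta)
  ov <- sw_overlap_all(cores, sw_core(toy$counts, toy$meta))
  fl <- enrichment_flags(ov)
  # every shared taxon in this toy is abundant in the water -> score 0
  expect_true(all(fl$score == 0))
  expect_false(any(fl$flag))
  expect_false(any(enrichment_flags(ov, dominance_cutoff = 100)$flag))
  # rare-seawater members do get scored: force one taxon rare in the reference
  ov_mod <- ov
  ov_mod$A$per_taxon$sw_pct[1] <- 0.001
  fl2 <- enrichment_flags(ov_mod)
  expect_equal(fl2$score[fl2$group == "A"],
               ov_mod$A$per_taxon$pct_of_core[1])
  expect_error(enrichment_flags(sw_overlap_all(
    cores, abundant_sw(toy$counts, toy$meta))), "seawater-core")
})

test_that("potential contamination lists abundant-SW taxa at trace core levels", {
  toy <- toy_dataset()
  cores <- extract_all_cores(toy$counts, toy$meta)
  ov <- sw_overlap_all(cores, sw_core(toy$counts, toy$meta))
  none <- potential_contamination(ov)
  expect_identical(nrow(none), 0L)
  ov$A$per_taxon$pct_of_core[1] <- 0.001  # trace in sponge, abundant in SW
  hit <- potential_contamination(ov)
  expect_identical(hit$group, "A")
  expect_identical(hit$taxon, ov$A$per_taxon$taxon[1])
})
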