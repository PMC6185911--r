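test_that("Shannon diversity matches direct evaluation in nats", {
  expect_equal(shannon(c(5, 5, 5, 5)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(10, 0, 0)), 0, tolerance = 1e-12)
  p <- c(1, 2, 3, 4) / 10
  expect_equal(shannon(c(1, 2, 3, 4)), -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon(c(0, 0)), "all-zero")
  # maximal at uniform composition
  set.seed(5)
  for (i in 1:10) {
    v <- rgamma(6, 1); v[1] <- v[1] + 0.1
    expect_lte(shannon(v), log(6) + 1e-12)
  }
})

test_that("Bray-Curtis follows the shared-abundance formula", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 1, 3), c = c(1, 2, 3), d = c(0, 0, 7))
  colnames(m) <- paste0("t", 1:3)
  D <- as.matrix(bray_curtis(m))
  expect_equal(D["a", "b"], 2 / 12, tolerance = 1e-12)
  expect_equal(D["a", "c"], 0, tolerance = 1e-12)
  # disjoint supports
  m2 <- rbind(a = c(3, 4, 0, 0), b = c(0, 0, 5, 1))
  expect_equal(as.vector(bray_curtis(m2)), 1, tolerance = 1e-12)
  expect_error(bray_curtis(m[1, , drop = FALSE]), "at least 2")
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("Bray-Curtis on relative abundances ignores sequencing depth", {
  set.seed(9)
  m <- matrix(rpois(30, 5) + 1L, 3, 10,
              dimnames = list(paste0("s", 1:3), paste0("t", 1:10)))
  tab <- count_table(m)
  scaled <- count_table(m * c(1L, 7L, 13L))  # per-sample depth rescaling
  D1 <- bray_curtis(to_relative_abundance(tab))
  D2 <- bray_curtis(to_relative_abundance(scaled))
  expect_equal(as.vector(D1), as.vector(D2), tolerance = 1e-12)
})

test_that("Spearman correlation equals Pearson on average ranks", {
  expect_equal(spearman(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:5) {
    x <- sample(1:5, 8, replace = TRUE)  # ties on purpose
    y <- rnorm(8)
    expect_equal(spearman(x, y)$rho, bf_spearman_rho(x, y), tolerance = 1e-12)
  }
  expect_false(spearman(rep(2, 5), 1:5)$defined)
  expect_error(spearman(1:3, 1:3), "at least 4")
  expect_error(spearman(1:5, 1:4), "equal length")
})

test_that("Kruskal-Wallis matches the rank-sum formula and is rank-invariant", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0,
               tolerance = 1e-12)
  sep <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(sep$H, 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7,
               tolerance = 1e-12)  # = 3.857...
  expect_equal(sep$df, 1)
  # invariant under monotone transformation
  g <- list(rnorm(5), rnorm(6) + 1, rnorm(4))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, function(v) exp(v)))$H,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty group")
})

test_that("average-linkage clustering reproduces brute-force agglomeration", {
  # two identical samples merge at height zero, tightest pair first
  m <- rbind(A = c(1, 0), B = c(1, 0), C = c(0, 1))
  D <- stats::dist(m)
  tree <- hcluster(D)
  expect_equal(min(tree$height), 0, tolerance = 1e-12)
  expect_setequal(tree$labels[-tree$merge[1, ]], c("A", "B"))

  d3 <- stats::as.dist(matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3,
                              dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  t3 <- hcluster(d3)
  expect_equal(t3$height, c(0.1, 0.9), tolerance = 1e-12)

  set.seed(14)
  m5 <- matrix(runif(25), 5, 5, dimnames = list(paste0("s", 1:5), NULL))
  D5 <- stats::dist(m5)
  expect_equal(sort(hcluster(D5)$height), bf_upgma_heights(D5),
               tolerance = 1e-12)
  expect_error(hcluster(stats::dist(m5[1, , drop = FALSE])), "at least 2")
})

test_that("dendrogram heights are input-order invariant and export to Newick", {
  set.seed(15)
  m <- matrix(runif(24), 6, 4, dimnames = list(paste0("s", 1:6), NULL))
  D1 <- stats::dist(m)
  perm <- sample(6)
  D2 <- stats::dist(m[perm, ])
  expect_equal(sort(hcluster(D1)$height), sort(hcluster(D2)$height),
               tolerance = 1e-12)
  nwk <- dendrogram_newick(hcluster(D1))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("s", 1:6))
  f <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(hcluster(D1), f)
  expect_identical(readLines(f), nwk)
})

test_that("heatmap export filters by abundance floor and attaches trees", {
  toy <- toy_dataset()
  cores <- extract_all_cores(toy$counts, toy$meta)
  ov <- sw_overlap_all(cores, sw_core(toy$counts, toy$meta))
  all_shared <- sort(unique(unlist(lapply(ov, function(o) o$per_taxon$taxon))))

  hm0 <- heatmap_export(ov, abundance_floor = 0)
  expect_setequal(colnames(hm0$matrix), all_shared)
  expect_s3_class(hm0$species_tree, "hclust")
  expect_warning(hm100 <- heatmap_export(ov, abundance_floor = 100), "empty")
  expect_identical(ncol(hm100$matrix), 0L)

  hm <- heatmap_export(ov, abundance_floor = 20)
  manual <- vapply(all_shared, function(t) {
    max(vapply(ov, function(o) {
      i <- match(t, o$per_taxon$taxon)
      if (is.na(i)) 0 else o$per_taxon$pct_of_core[i]
    }, numeric(1)))
  }, numeric(1))
  expect_setequal(colnames(hm$matrix), names(manual)[manual > 20])
  expect_true(all(hm$long$taxon %in% colnames(hm$matrix)))
})
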