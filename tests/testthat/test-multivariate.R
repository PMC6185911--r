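test_that("PERMANOVA reproduces the distance sum-of-squares decomposition", {
  D <- four_point_D()
  g <- c(s1 = "x", s2 = "x", s3 = "y", s4 = "y")
  res <- permanova(D, g, n_perm = 99, seed = 1)
  oracle <- bf_permanova(D, g[attr(D, "Labels")])
  expect_equal(res$R2, oracle$R2, tolerance = 1e-12)
  expect_equal(res$pseudo_F, oracle$F, tolerance = 1e-12)
  expect_true(res$p_perm >= 1 / 100 && res$p_perm <= 1)
  expect_error(permanova(D, rep("x", 4)), "2 groups")
})

test_that("PERMANOVA agrees with the classical ANOVA F on Euclidean 1-D data", {
  set.seed(31)
  x <- c(rnorm(6), rnorm(6, 1.5))
  names(x) <- paste0("s", 1:12)
  g <- rep(c("a", "b"), each = 6)
  names(g) <- names(x)
  res <- permanova(stats::dist(x), g, n_perm = 99, seed = 2)
  f_classic <- summary(stats::aov(x ~ g))[[1]]$`F value`[1]
  expect_equal(res$pseudo_F, f_classic, tolerance = 1e-10)
})

test_that("PERMANOVA matches vegan's implementation on a community matrix", {
  set.seed(32)
  m <- matrix(rpois(80, 8), 8, 10, dimnames = list(paste0("s", 1:8), NULL))
  D <- vegan::vegdist(m, "bray")
  g <- rep(c("u", "v"), each = 4)
  res <- permanova(D, stats::setNames(g, paste0("s", 1:8)), n_perm = 199, seed = 3)
  ad <- vegan::adonis2(D ~ g, permutations = 199)
  expect_equal(res$R2, ad$R2[1], tolerance = 1e-10)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA is invariant to sample reordering and seed-reproducible", {
  set.seed(33)
  m <- matrix(rpois(60, 6), 6, 10, dimnames = list(paste0("s", 1:6), NULL))
  D <- vegan::vegdist(m, "bray")
  g <- stats::setNames(rep(c("a", "b"), 3), paste0("s", 1:6))
  perm <- sample(6)
  D2 <- stats::as.dist(as.matrix(D)[perm, perm])
  expect_equal(permanova(D, g, 49, seed = 5)$R2,
               permanova(D2, g, 49, seed = 5)$R2, tolerance = 1e-12)
  expect_identical(permanova(D, g, 199, seed = 7)$p_perm,
                   permanova(D, g, 199, seed = 7)$p_perm)
  # identical points within groups: SS_within = 0 handled as infinite F
  m0 <- rbind(a1 = c(1, 0), a2 = c(1, 0), b1 = c(0, 1), b2 = c(0, 1))
  res0 <- permanova(stats::dist(m0),
                    stats::setNames(c("a", "a", "b", "b"), rownames(m0)),
                    n_perm = 99)
  expect_identical(res0$pseudo_F, Inf)
  expect_equal(res0$p_perm, 1 / 100)
})

test_that("PERMDISP distances and F match vegan's centroid betadisper", {
  set.seed(41)
  m <- matrix(rpois(120, 7), 12, 10, dimnames = list(paste0("s", 1:12), NULL))
  D <- vegan::vegdist(m, "bray")
  g <- factor(rep(c("a", "b"), c(4, 8)))
  res <- permdisp(D, stats::setNames(as.character(g), paste0("s", 1:12)),
                  bias_adjust = TRUE, n_perm = 99, seed = 4)
  bd <- vegan::betadisper(D, g, type = "centroid", bias.adjust = TRUE)
  expect_equal(unname(res$distances), unname(bd$distances), tolerance = 1e-8)
  expect_equal(res$F, anova(bd)$`F value`[1], tolerance = 1e-8)
  # and without the bias adjustment
  res2 <- permdisp(D, stats::setNames(as.character(g), paste0("s", 1:12)),
                   bias_adjust = FALSE, n_perm = 99, seed = 4)
  bd2 <- vegan::betadisper(D, g, type = "centroid")
  expect_equal(unname(res2$distances), unname(bd2$distances), tolerance = 1e-8)
})

test_that("PERMDISP boundary behaviour: identical points and size-1 groups", {
  m <- rbind(a1 = c(1, 0), a2 = c(1, 0), a3 = c(1, 0),
             b1 = c(0.2, 1), b2 = c(0.9, 0.1), b3 = c(0.4, 0.6))
  D <- stats::dist(m)
  g <- stats::setNames(rep(c("a", "b"), each = 3), rownames(m))
  res <- permdisp(D, g, n_perm = 99, seed = 1)
  expect_equal(unname(res$group_means["a"]), 0, tolerance = 1e-12)
  expect_gt(unname(res$group_means["b"]), 0)
  g1 <- stats::setNames(c("a", rep("b", 5)), rownames(m))
  expect_error(permdisp(D, g1), "size 1")
})

test_that("IndVal equals the exhaustive Dufrene-Legendre statistic", {
  # 8 samples, 3 taxa, 2 groups
  m <- rbind(
    g1_1 = c(0.5, 0.2, 0.0), g1_2 = c(0.4, 0.3, 0.0),
    g1_3 = c(0.6, 0.1, 0.0), g1_4 = c(0.5, 0.0, 0.0),
    g2_1 = c(0.0, 0.2, 0.3), g2_2 = c(0.0, 0.3, 0.4),
    g2_3 = c(0.0, 0.2, 0.0), g2_4 = c(0.0, 0.1, 0.5))
  colnames(m) <- c("only1", "shared", "mostly2")
  g <- rep(c("g1", "g2"), each = 4)
  res <- indval(m, stats::setNames(g, rownames(m)), n_perm = 199, seed = 6)
  oracle <- bf_indval(m, g)
  best <- apply(oracle, 2, max)
  expect_equal(stats::setNames(res$indval, res$taxon), best, tolerance = 1e-12)
  expect_identical(res$group[res$taxon == "only1"], "g1")
  expect_equal(res$indval[res$taxon == "only1"], 1, tolerance = 1e-12)

  # equal means, full occurrence -> A = 0.5, B = 1
  m2 <- matrix(0.3, 6, 1, dimnames = list(paste0("s", 1:6), "even"))
  res2 <- indval(m2, stats::setNames(rep(c("a", "b"), 3), paste0("s", 1:6)),
                 n_perm = 99, seed = 1)
  expect_equal(res2$indval, 0.5, tolerance = 1e-12)
})

test_that("IndVal contract: row scaling matters unless the table is renormalised", {
  set.seed(55)
  m <- matrix(rgamma(40, 1), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  m <- m / rowSums(m)
  g <- stats::setNames(rep(c("a", "b"), each = 4), rownames(m))
  base <- indval(m, g, n_perm = 49, seed = 2)

  scaled <- m; scaled[3, ] <- scaled[3, ] * 5  # abundances as given change A
  res_scaled <- indval(scaled, g, n_perm = 49, seed = 2)
  expect_false(isTRUE(all.equal(base$indval, res_scaled$indval)))

  renorm <- scaled / rowSums(scaled)            # renormalised: contract restored
  res_renorm <- indval(renorm, g, n_perm = 49, seed = 2)
  expect_equal(base$indval, res_renorm$indval, tolerance = 1e-12)
})

test_that("permutation p-values obey the add-one rule and seeding", {
  set.seed(66)
  m <- matrix(rpois(60, 5), 6, 10, dimnames = list(paste0("s", 1:6), NULL))
  D <- vegan::vegdist(m, "bray")
  g <- stats::setNames(rep(c("a", "b"), 3), paste0("s", 1:6))
  for (fn in list(function(s) permanova(D, g, 99, seed = s)$p_perm,
                  function(s) permdisp(D, g, n_perm = 99, seed = s)$p_perm)) {
    p1 <- fn(9); p2 <- fn(9); p3 <- fn(10)
    expect_identical(p1, p2)
    expect_gte(p1, 1 / 100)
    expect_lte(p1, 1)
  }
  iv1 <- indval(m / rowSums(m), g, n_perm = 99, seed = 3)
  iv2 <- indval(m / rowSums(m), g, n_perm = 99, seed = 3)
  expect_identical(iv1$p_perm, iv2$p_perm)
  expect_true(all(iv1$p_perm >= 1 / 100 & iv1$p_perm <= 1))
})

test_that("taxa absent everywhere are excluded from IndVal with a note", {
  m <- cbind(t1 = c(0.6, 0.4, 0.5, 0.7), t2 = c(0, 0, 0, 0))
  rownames(m) <- paste0("s", 1:4)
  g <- stats::setNames(rep(c("a", "b"), 2), rownames(m))
  expect_message(res <- indval(m, g, n_perm = 49, seed = 1), "absent")
  expect_identical(res$taxon, "t1")
})
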